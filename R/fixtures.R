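# The worked-example sentences bundled with the package: published
# abstract sentences (identified by PMID) illustrating positive and
# negative rate-change regulation events and direct vs indirect evidence.

FIXTURE_DATA <- list(
  list(pmid = "16400179", label = "positive", subtype = "direct",
       source = "instance", example = NA_integer_,
       text = paste0(
         "In contrast, degradation of MTH1 is reinforced by glucose ",
         "repression of MTH1 expression: disappearance of MTH1 is slowed ",
         "when glucose repression of MTH1 expression is prevented, and this ",
         "results in a delay in induction of HXT3 expression in response to ",
         "glucose.")),
  list(pmid = "20303984", label = "negative", subtype = "n/a",
       source = "instance", example = NA_integer_,
       text = paste0(
         "As the translational control in the expression of cycle proteins ",
         "Cdc13 and Cdc25 constructs positive feedback loops, the dynamical ",
         "activities of the key components undergoes a rapid rising after a ",
         "preliminary stage of slow increase.")),
  list(pmid = "15546622", label = "positive", subtype = "direct",
       source = "example", example = 1L,
       text = paste0(
         "Endogenous Mdm2 is tethered in vivo, presumably via p53, to ",
         "chromatin comprising the p53-responsive p21(waf1) promoter, and ",
         "Mdm2 overexpression enhances protein ubiquitylation in the ",
         "vicinity of a p53 binding site within that promoter.")),
  list(pmid = "20008511", label = "positive", subtype = "direct",
       source = "example", example = 2L,
       text = paste0(
         "Deletion of CHZ1 led to reduced ubiquitination of ",
         "subtelomere-associated H2B, reduced subtelomeric H3K79 ",
         "dimethylation, and increased binding of Sir3p, and Sir4p at ",
         "telomere-distal euchromatin regions, correlating with decreased ",
         "gene expression in subtelomeric regions.")),
  list(pmid = "21526151", label = "positive", subtype = "direct",
       source = "example", example = 3L,
       text = paste0(
         "The cofactor npl4-1 and ufd1-2 mutants also exhibit G1 delay and ",
         "reduced CLN1 promoter activity at 38.5 degrees C, suggesting that ",
         "Npl4-Ufd1 complex mediates the function of Cdc48 at G1.")),
  list(pmid = "12737807", label = "negative", subtype = "n/a",
       source = "example", example = 4L,
       text = paste0(
         "We show here that the role of these proteins is instead to ",
         "promote nucleolar segregation, including release of the Cdc14 ",
         "phosphatase required for Cdk1 inactivation and disassembly of the ",
         "anaphase I spindle.")),
  list(pmid = "18408730", label = "negative", subtype = "n/a",
       source = "example", example = 5L,
       text = paste0(
         "Here we show that two highly conserved ATP-dependent ",
         "chromatin-remodeling complexes in Saccharomyces cerevisiae, Isw2 ",
         "and Ino80, function in parallel to promote replication fork ",
         "progression.")),
  list(pmid = "16997274", label = "negative", subtype = "n/a",
       source = "example", example = 6L,
       text = paste0(
         "Of the single codon changes, mutation of the first ATG (ATG1) ",
         "resulted in the largest increase of the reporter gene ",
         "PIS1(promoter)-lacZ expression.")),
  list(pmid = "12086182", label = "positive", subtype = "indirect_I",
       source = "example", example = 7L,
       text = paste0(
         "The results indicate that during the first hours of ",
         "microvinification there is an increase in the GPDI mRNA levels ",
         "with a maximum about one hour after inoculation, and a decrease ",
         "in the amount of HSP12 and HSP104 mRNAs, although with ",
         "differences between them.")),
  list(pmid = "8483452", label = "positive", subtype = "indirect_II",
       source = "example", example = 8L,
       text = paste0(
         "Four different conditions were found to cause expression of Ime1 ",
         "protein in vegetative cultures: elevated transcription levels due ",
         "to the presence of IME1 on a multicopy plasmid; elevated ",
         "transcription provided by a Gal-IME1 construct; G1 arrest due to ",
         "alpha-factor treatment; G1 arrest following mild heat-shock ",
         "treatment of cdc28 diploids."))
)

#' Bundled example sentences with gold labels
#'
#' Ten published abstract sentences (by PMID) used as worked examples:
#' two labelled instances (one positive, one negative) and eight numbered
#' examples covering positive rate-change patterns, negative (veto)
#' patterns, and indirect-evidence subclasses I (incomplete regulation
#' information) and II (genetic-engineering manipulation).
#'
#' @param annotate run the preprocessing chain and attach a toy parse?
#' @param resources resource list (used when `annotate = TRUE`).
#' @return list of `rc_sentence` objects with `label`, `subtype`,
#'   `source` ("instance" or "example") and `example` (number or `NA`).
#' @export
fixture_sentences <- function(annotate = TRUE,
                              resources = load_default_resources()) {
  lapply(FIXTURE_DATA, function(f) {
    s <- structure(list(pmid = f$pmid, index = 0L, raw = f$text,
                        tokens = NULL, gene_mentions = NULL, parse = NULL),
                   class = "rc_sentence")
    if (annotate) {
      s <- preprocess_sentence(s, resources$gene_dict, resources$norm_dict)
      s$parse <- typed_chain_parse(nrow(s$tokens))
    }
    s$label <- f$label
    s$subtype <- f$subtype
    s$source <- f$source
    s$example <- f$example
    s$planted_nodes <- character(0)
    s
  })
}

#' Bundled example sentences wrapped as abstracts
#'
#' Each fixture sentence is embedded in a two-sentence abstract (a short
#' lead-in followed by the sentence verbatim), for exercising the
#' segmentation and filtering stages end to end.
#'
#' @return list of `rc_abstract` objects, one per fixture PMID.
#' @export
fixture_abstracts <- function() {
  lapply(FIXTURE_DATA, function(f) {
    abstract(f$pmid, paste("We examined transcriptional regulation in",
                           "budding yeast.", f$text))
  })
}
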