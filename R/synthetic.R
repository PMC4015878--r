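# Synthetic labeled-corpus generator: slot-template sentences carrying
# the statistical and textual structure the pipeline assumes (two or more
# gene mentions, co-occurring regulate and rate-change trigger words,
# planted ontology patterns, direct/indirect evidence geometry on a toy
# parse), so every stage is testable without downloads.

#' Generator configuration
#'
#' Defaults emulate the annotated-corpus composition: 1309 sentences,
#' 357/1309 positives, 211/357 of positives carrying direct evidence, and
#' a negative mix proportional to the negative-ontology class tallies
#' (cell cycle 71, DNA replication 49, translation 35, remainder other
#' processes).
#'
#' @param n_sentences number of sentences to generate.
#' @param positive_fraction fraction of positive instances.
#' @param direct_fraction fraction of positives with direct evidence.
#' @param negative_mix named proportions over `cell_cycle`,
#'   `dna_replication`, `translation`, `other_process`; must sum to 1.
#' @param label_noise probability of independently flipping each gold
#'   label.
#' @param seed integer RNG seed.
#' @return object of class `rc_generator_config`.
#' @export
generator_config <- function(n_sentences = 1309L,
                             positive_fraction = 357 / 1309,
                             direct_fraction = 211 / 357,
                             negative_mix = c(cell_cycle = 71, dna_replication = 49,
                                              translation = 35, other_process = 797) / 952,
                             label_noise = 0,
                             seed = 1L) {
  stopifnot(n_sentences >= 1,
            positive_fraction >= 0, positive_fraction <= 1,
            direct_fraction >= 0, direct_fraction <= 1,
            label_noise >= 0, label_noise <= 1)
  req <- c("cell_cycle", "dna_replication", "translation", "other_process")
  if (!setequal(names(negative_mix), req))
    stop("negative_mix must name exactly: ", paste(req, collapse = ", "))
  if (any(negative_mix < 0) || abs(sum(negative_mix) - 1) > 1e-8)
    stop("negative_mix must be nonnegative and sum to 1")
  structure(list(n_sentences = as.integer(n_sentences),
                 positive_fraction = positive_fraction,
                 direct_fraction = direct_fraction,
                 negative_mix = negative_mix[req],
                 label_noise = label_noise,
                 seed = as.integer(seed)),
            class = "rc_generator_config")
}

# Filler vocabulary guaranteed disjoint from trigger words and ontology
# pattern keywords.
FILLERS <- c("the", "cells", "under", "conditions", "observed", "samples",
             "analysis", "growth", "medium", "during", "cultures", "strain")

# Neutral regulate triggers for positive templates (no overlap with
# ontology pattern keywords, so gene-keyword distances stay by design).
NEUTRAL_REG <- c("regulate", "induce", "control", "mediate", "modulate",
                 "stimulate", "target", "inhibit", "suppress")

# Typed chain parse: token i hangs off token i-1 with a dependency label
# cycled deterministically, so path lengths equal position distances.
typed_chain_parse <- function(n_tokens) {
  types <- c("nsubj", "dobj", "prep", "pobj", "amod", "nmod", "conj", "det")
  if (n_tokens == 1L) return(chain_parse(1L))
  dependency_parse(
    data.frame(head = seq_len(n_tokens - 1L), dep = 2:n_tokens,
               type = rep_len(types, n_tokens - 1L), stringsAsFactors = FALSE),
    n_tokens, 1L)
}

#' Generate a synthetic labeled corpus
#'
#' Every sentence carries at least two gene mentions, one regulate-lexicon
#' word and one rate-change-lexicon word (so all sentences satisfy the
#' corpus preconditions). Positives embed the keywords of one rate-change
#' ontology pattern and no negative pattern; negatives embed a negative
#' ontology pattern from the configured mix, half of them alongside
#' positive-looking keywords to mimic the false-positive phenomenon the
#' veto ontology exists for. Direct positives place a gene within
#' toy-parse distance 3 of the planted keywords; indirect positives place
#' them farther (subclass I) or add genetic-engineering markers
#' ("multicopy plasmid" / "construct", subclass II). With `label_noise`
#' > 0 each gold label flips independently; the pre-noise label is kept
#' in `planted_label`.
#'
#' @param config an [generator_config()].
#' @param resources resource list from [load_default_resources()].
#' @return list of annotated `rc_sentence` objects with extra fields
#'   `label` (post-noise gold label), `planted_label`, `subtype`
#'   (`direct`, `indirect_I`, `indirect_II` or `n/a`), `planted_nodes`
#'   and a toy `parse`.
#' @export
generate_corpus <- function(config = generator_config(),
                            resources = load_default_resources()) {
  pos_onto <- resources$ontology_positive
  neg_onto <- resources$ontology_negative
  gene_pool <- sort(unique(resources$gene_dict$map))
  rate_pool <- setdiff(resources$ratechange_lexicon$heads,
                       c(grep(" ", resources$ratechange_lexicon$heads, value = TRUE)))
  reg_pool <- resources$regulate_lexicon$heads
  neg_nodes <- names(config$negative_mix)
  neg_patterns_by_node <- lapply(neg_nodes, function(nd)
    Filter(function(p) p$node_id == nd, neg_onto$patterns))
  names(neg_patterns_by_node) <- neg_nodes

  with_seed(config$seed, {
    lapply(seq_len(config$n_sentences), function(i) {
      genes <- sample(gene_pool, 2L)
      rate <- sample(rate_pool, 1L)
      positive <- stats::runif(1) < config$positive_fraction
      planted <- character(0)
      if (positive) {
        reg <- sample(NEUTRAL_REG, 1L)
        pat <- sample(pos_onto$patterns, 1L)[[1]]
        planted <- pat$node_id
        direct <- stats::runif(1) < config$direct_fraction
        subtype <- if (direct) "direct" else sample(c("indirect_I", "indirect_II"), 1L)
        tokens <- switch(subtype,
          direct = c(genes[1L], rate, reg, "of", genes[2L], pat$keywords,
                     "in", sample(FILLERS, 2L)),
          indirect_I = c(genes[1L], "and", genes[2L], rate, reg,
                         sample(FILLERS, 5L), pat$keywords),
          indirect_II = c(genes[1L], rate, reg, "of", genes[2L],
                          "on", "a", "multicopy", "plasmid", "construct",
                          pat$keywords))
        label <- "positive"
      } else {
        reg <- sample(reg_pool, 1L)
        node <- sample(neg_nodes, 1L, prob = config$negative_mix)
        pats <- neg_patterns_by_node[[node]]
        if (length(pats) == 0L) stop("negative mix names a node with no patterns: ", node)
        pat <- pats[[sample.int(length(pats), 1L)]]
        planted <- pat$node_id
        kw <- pat$keywords
        if (stats::runif(1) < 0.5) {  # false-positive mimic
          mimic <- sample(pos_onto$patterns, 1L)[[1]]
          kw <- c(kw, mimic$keywords)
          planted <- c(planted, mimic$node_id)
        }
        subtype <- "n/a"
        tokens <- c(genes[1L], rate, reg, "of", genes[2L], kw,
                    "in", sample(FILLERS, 2L))
        label <- "negative"
      }
      raw <- paste0(paste(tokens, collapse = " "), ".")
      s <- structure(list(pmid = sprintf("SYN%06d", i), index = 0L, raw = raw,
                          tokens = NULL, gene_mentions = NULL, parse = NULL),
                     class = "rc_sentence")
      s <- preprocess_sentence(s, resources$gene_dict, resources$norm_dict)
      s$parse <- typed_chain_parse(nrow(s$tokens))
      s$planted_label <- label
      s$label <- if (config$label_noise > 0 && stats::runif(1) < config$label_noise) {
        if (label == "positive") "negative" else "positive"
      } else label
      s$subtype <- subtype
      s$planted_nodes <- sort(unique(planted))
      s
    })
  })
}

#' Serialize a generated corpus as a TSV table
#'
#' @param corpus list from [generate_corpus()] or [fixture_sentences()].
#' @return data.frame with `pmid`, `sentence_index`, `text`, `label`,
#'   `evidence_subtype`, `planted_nodes`.
#' @export
corpus_table <- function(corpus) {
  do.call(rbind, lapply(corpus, function(s) data.frame(
    pmid = s$pmid, sentence_index = s$index, text = s$raw,
    label = s$label %||% NA_character_,
    evidence_subtype = s$subtype %||% NA_character_,
    planted_nodes = paste(s$planted_nodes %||% character(0), collapse = ","),
    stringsAsFactors = FALSE)))
}
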