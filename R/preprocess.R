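# Sentence segmentation, tokenization, POS tagging, gene mention
# recognition and word normalization.

#' Construct a raw abstract
#'
#' @param pmid nonempty PubMed identifier string.
#' @param text nonempty abstract body.
#' @return an object of class `rc_abstract`.
#' @export
abstract <- function(pmid, text) {
  pmid <- as.character(pmid)
  if (!nzchar(pmid)) stop("pmid must be nonempty")
  if (!nzchar(trimws(text))) stop("abstract text must be nonempty")
  structure(list(pmid = pmid, text = text), class = "rc_abstract")
}

# Sentence-final periods are not split when the preceding token is a known
# abbreviation; "S." style genus initials are the common biomedical case.
ABBREVIATIONS <- c("S.", "sp.", "spp.", "e.g.", "i.e.", "cf.", "vs.", "al.", "ca.")

#' Segment an abstract into sentences
#'
#' Splits on sentence-final `.`, `!` or `?` followed by whitespace and an
#' upper-case letter, digit or quote, skipping boundaries whose preceding
#' token is a known abbreviation (`S.`, `sp.`, `e.g.`, `i.e.`, ...).
#' Concatenating the returned raw sentences reproduces the abstract text
#' modulo whitespace.
#'
#' @param ab an `rc_abstract` (or list with `pmid` and `text`).
#' @return list of `rc_sentence` objects carrying `pmid`, 0-based `index`
#'   and `raw` text (no tokens yet).
#' @export
segment_sentences <- function(ab) {
  text <- ab$text
  hits <- gregexpr("[.!?]+(?=\\s+[\"'(]?[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (hits[1] != -1L) {
    ends <- as.integer(hits) + attr(hits, "match.length") - 1L
    for (e in ends) {
      prefix <- substr(text, 1L, e)
      last_tok <- sub(".*[\\s(]", "", prefix, perl = TRUE)
      if (last_tok %in% ABBREVIATIONS) next
      cuts <- c(cuts, e)
    }
  }
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, nchar(text))
  raws <- trimws(substring(text, starts, stops))
  raws <- raws[nzchar(raws)]
  lapply(seq_along(raws), function(i) {
    structure(list(pmid = ab$pmid, index = i - 1L, raw = raws[i],
                   tokens = NULL, gene_mentions = NULL, parse = NULL),
              class = "rc_sentence")
  })
}

#' @export
print.rc_sentence <- function(x, ...) {
  cat("<rc_sentence ", x$pmid, "#", x$index,
      if (!is.null(x$tokens)) paste0(", ", nrow(x$tokens), " tokens"),
      ">\n  ", substr(x$raw, 1, 72), if (nchar(x$raw) > 72) "...", "\n",
      sep = "")
  invisible(x)
}

# Word tokenizer: alphanumeric runs (keeps gene symbols like MTH1, p21,
# H2B intact; splits hyphenated compounds) plus single punctuation tokens.
tokenize_raw <- function(raw) {
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", raw)[[1]]
  regmatches(raw, list(m))[[1]]
}

# Closed-class word list for the rule-cascade tagger.
CLOSED_CLASS <- c(
  the = "DT", a = "DT", an = "DT", this = "DT", that = "DT", these = "DT",
  those = "DT", each = "DT", all = "DT", both = "DT", several = "JJ",
  some = "DT", any = "DT", no = "DT",
  of = "IN", "in" = "IN", on = "IN", at = "IN", by = "IN", "for" = "IN",
  with = "IN", from = "IN", via = "IN", within = "IN", into = "IN",
  over = "IN", after = "IN", before = "IN", during = "IN", between = "IN",
  under = "IN", about = "IN", through = "IN", as = "IN", due = "JJ",
  to = "TO", and = "CC", or = "CC", but = "CC", nor = "CC",
  is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB",
  been = "VBN", being = "VBG", am = "VBP",
  has = "VBZ", have = "VBP", had = "VBD", do = "VBP", does = "VBZ",
  did = "VBD", can = "MD", could = "MD", may = "MD", might = "MD",
  will = "MD", would = "MD", shall = "MD", should = "MD", must = "MD",
  not = "RB", also = "RB", here = "RB", there = "EX", when = "WRB",
  where = "WRB", which = "WDT", who = "WP", whose = "WP$", what = "WP",
  we = "PRP", it = "PRP", they = "PRP", its = "PRP$", their = "PRP$",
  our = "PRP$", i = "PRP", he = "PRP", she = "PRP",
  than = "IN", "if" = "IN", although = "IN", because = "IN", "while" = "IN",
  however = "RB", thus = "RB", therefore = "RB", moreover = "RB",
  instead = "RB", only = "RB", very = "RB", more = "RBR", most = "RBS",
  less = "RBR", least = "RBS", first = "JJ", second = "JJ", third = "JJ",
  one = "CD", two = "CD", three = "CD", four = "CD", five = "CD",
  six = "CD", seven = "CD", eight = "CD", nine = "CD", ten = "CD"
)

# Common verb stems so that "enhances"/"enhanced" tag as verbs rather than
# plural nouns; drawn from the regulation/rate-change trigger vocabulary
# plus frequent reporting verbs.
VERB_STEMS <- c(
  "regulate", "induce", "repress", "express", "activate", "transcribe",
  "bind", "inhibit", "suppress", "control", "mediate", "modulate",
  "promote", "degrade", "stimulate", "silence", "interact",
  "phosphorylate", "ubiquitinate", "methylate", "acetylate", "target",
  "respond", "accelerate", "extend", "increase", "rise", "peak",
  "enhance", "assist", "block", "prevent", "abolish", "reduce",
  "decrease", "compromise", "sustain", "alleviate", "decline", "lower",
  "diminish", "limit", "fail", "lack", "delay", "slow", "alter", "exert",
  "show", "indicate", "suggest", "demonstrate", "result", "require",
  "contain", "include", "involve", "cause", "lead", "affect", "occur",
  "remain", "provide", "perform", "undergo", "found", "find", "confirm",
  "correlate", "exhibit", "elevate", "reinforce", "construct", "tether",
  "function", "comprise", "remodel", "arrest", "release", "change"
)

# Deterministic rule-cascade Penn Treebank tagger: closed-class lookup,
# then orthographic cues (digits/case for bio-entity nouns), then suffix
# heuristics. Lightweight by design; tags feed only the "noun-tagged gene"
# filter condition and the keyword-tag feature family.
pos_tag_tokens <- function(surface) {
  lower <- tolower(surface)
  vapply(seq_along(surface), function(i) {
    s <- surface[i]; l <- lower[i]
    if (grepl("^[^A-Za-z0-9]+$", s)) {
      return(if (s %in% c(".", ",", ":", ";", "(", ")", "\"", "'")) s else "SYM")
    }
    if (!is.na(CLOSED_CLASS[l])) return(unname(CLOSED_CLASS[l]))
    if (grepl("^[0-9]+$", s)) return("CD")
    # gene-symbol-like orthography: digits inside, all-caps, or internal caps
    if (grepl("[0-9]", s)) return("NN")
    if (nchar(s) > 1L && s == toupper(s)) return("NN")
    if (grepl("[A-Z]", substr(s, 2, nchar(s)))) return("NN")
    if (endsWith(l, "ly")) return("RB")
    if (endsWith(l, "ing")) {
      stem <- sub("ing$", "", l)
      if (stem %in% VERB_STEMS || paste0(stem, "e") %in% VERB_STEMS) return("VBG")
      return("NN")
    }
    if (endsWith(l, "ed")) return("VBN")
    if (l %in% VERB_STEMS) return("VB")
    if (endsWith(l, "s") && (sub("s$", "", l) %in% VERB_STEMS ||
                             sub("es$", "", l) %in% VERB_STEMS)) return("VBZ")
    if (grepl("(tion|sion|ment|ness|ity|ance|ence|ase|ism|osis|phase|some|mere)s?$", l))
      return(if (endsWith(l, "s") && !grepl("(ness|osis)$", l)) "NNS" else "NN")
    if (grepl("(al|ive|ous|ic|able|ible|ant|ent|ary|ar|ile)$", l)) return("JJ")
    if (endsWith(l, "s")) return("NNS")
    "NN"
  }, character(1))
}

#' Tokenize a sentence and assign part-of-speech tags
#'
#' Word tokens are maximal alphanumeric runs (gene symbols such as `MTH1`
#' or `H2B` stay intact; hyphenated compounds split); punctuation marks are
#' their own tokens. Tags come from a deterministic rule-cascade Penn
#' Treebank tagger (closed-class lexicon, orthographic cues, suffix
#' heuristics); "tagged as noun" downstream means an `NN`-prefixed tag.
#'
#' @param sentence an `rc_sentence` with `raw` set.
#' @return the sentence with a `tokens` data.frame (`surface`, `pos`,
#'   `normalized` = `NA` until [normalize_sentence()], `is_gene` = FALSE).
#' @export
tokenize_and_tag <- function(sentence) {
  if (is.null(sentence$raw) || !nzchar(trimws(sentence$raw)))
    stop("cannot tokenize an empty sentence")
  surface <- tokenize_raw(sentence$raw)
  sentence$tokens <- data.frame(
    surface = surface,
    pos = pos_tag_tokens(surface),
    normalized = NA_character_,
    is_gene = FALSE,
    stringsAsFactors = FALSE
  )
  sentence
}

#' Recognize gene mentions by dictionary matching
#'
#' Case-insensitive exact token matching against the synonym dictionary,
#' longest non-overlapping match first (left to right). Covered tokens get
#' `is_gene = TRUE`.
#'
#' @param sentence a tokenized `rc_sentence`.
#' @param gene_dict an `rc_gene_dict` from [read_gene_dict()].
#' @return the sentence with `gene_mentions`: data.frame of `start`, `end`
#'   (token indices, inclusive) and `gene_id`.
#' @export
recognize_genes <- function(sentence, gene_dict) {
  if (is.null(sentence$tokens)) stop("tokenize the sentence first")
  toks <- toupper(sentence$tokens$surface)
  n <- length(toks)
  mentions <- list()
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (k in seq(min(gene_dict$max_len, n - i + 1L), 1L)) {
      cand <- paste(toks[i:(i + k - 1L)], collapse = " ")
      if (cand %in% names(gene_dict$map)) { hit_len <- k; break }
    }
    if (hit_len > 0L) {
      cand <- paste(toks[i:(i + hit_len - 1L)], collapse = " ")
      mentions[[length(mentions) + 1L]] <- data.frame(
        start = i, end = i + hit_len - 1L,
        gene_id = unname(gene_dict$map[cand]), stringsAsFactors = FALSE)
      sentence$tokens$is_gene[i:(i + hit_len - 1L)] <- TRUE
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  sentence$gene_mentions <- if (length(mentions)) {
    do.call(rbind, mentions)
  } else {
    data.frame(start = integer(0), end = integer(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  }
  sentence
}

#' Normalize sentence tokens
#'
#' Gene tokens become the placeholder `"genename"`; dictionary keywords are
#' replaced by their head form (the first column of the normalization
#' dictionary); everything else is lower-cased. Applied after tagging so
#' tags reflect the original surface forms. Idempotent.
#'
#' @param sentence an `rc_sentence` with genes recognized.
#' @param norm_map named character vector from [read_norm_dict()].
#' @return the sentence with the `normalized` token column filled.
#' @export
normalize_sentence <- function(sentence, norm_map) {
  if (is.null(sentence$tokens)) stop("tokenize the sentence first")
  if (is.null(sentence$gene_mentions)) stop("recognize genes first")
  lower <- tolower(sentence$tokens$surface)
  norm <- ifelse(lower %in% names(norm_map), unname(norm_map[lower]), lower)
  norm[sentence$tokens$is_gene] <- "genename"
  norm[lower == "genename"] <- "genename"
  sentence$tokens$normalized <- norm
  sentence
}

#' Run the full preprocessing chain on one sentence
#'
#' @param sentence an `rc_sentence` with `raw` set.
#' @param gene_dict an `rc_gene_dict`.
#' @param norm_map normalization map.
#' @return tokenized, tagged, gene-annotated, normalized sentence.
#' @export
preprocess_sentence <- function(sentence, gene_dict, norm_map) {
  normalize_sentence(
    recognize_genes(tokenize_and_tag(sentence), gene_dict), norm_map)
}

#' Preprocess an abstract into annotated sentences
#'
#' @param ab an `rc_abstract`.
#' @inheritParams preprocess_sentence
#' @return list of annotated `rc_sentence` objects.
#' @export
preprocess_abstract <- function(ab, gene_dict, norm_map) {
  lapply(segment_sentences(ab), preprocess_sentence,
         gene_dict = gene_dict, norm_map = norm_map)
}

#' Read abstracts from TSV or MEDLINE flat files
#'
#' The TSV layout is two header-named columns `pmid` and `text`. MEDLINE
#' flat files are parsed for `PMID-` and `AB  -` fields (with standard
#' continuation-line indentation).
#'
#' @param path input file.
#' @param format `"tsv"` or `"medline"`.
#' @return list of `rc_abstract` objects.
#' @export
read_abstracts <- function(path, format = c("tsv", "medline")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", quote = "")
    stopifnot(all(c("pmid", "text") %in% names(df)))
    return(lapply(seq_len(nrow(df)), function(i) abstract(df$pmid[i], df$text[i])))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- list(); pmid <- NULL; ab <- NULL; in_ab <- FALSE
  flush <- function() {
    if (!is.null(pmid) && !is.null(ab))
      records[[length(records) + 1L]] <<- abstract(pmid, paste(ab, collapse = " "))
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 4)
    if (grepl("^PMID", ln)) {
      flush(); pmid <- trimws(sub("^PMID- *", "", ln)); ab <- NULL; in_ab <- FALSE
    } else if (grepl("^AB  -", ln)) {
      ab <- trimws(sub("^AB  - *", "", ln)); in_ab <- TRUE
    } else if (in_ab && grepl("^\\s{6}", ln)) {
      ab <- c(ab, trimws(ln))
    } else if (nzchar(trimws(tag))) {
      in_ab <- FALSE
    }
  }
  flush()
  records
}
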