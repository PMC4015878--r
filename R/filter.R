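# Cosine-similarity sentence filtering against trigger-word lexicons.

#' Binary sentence vector over a lexicon
#'
#' The indicator vector has one dimension per lexicon entry, with a one in
#' each dimension whose entry occurs among the sentence's normalized
#' tokens (binary, not counts; multi-word entries match as contiguous
#' n-grams).
#'
#' @param sentence normalized `rc_sentence` or character vector of
#'   normalized tokens.
#' @param lexicon an `rc_lexicon`.
#' @return object of class `rc_sentence_vector`: list with `lexicon_name`,
#'   `indicator` (0/1 integer vector of length `size_n`) and `m` (number of
#'   ones).
#' @export
sentence_vector <- function(sentence, lexicon) {
  if (!inherits(lexicon, "rc_lexicon") || lexicon$size_n < 1L)
    stop("empty lexicon")
  tokens <- normalized_tokens(sentence)
  ind <- as.integer(match_entries(tokens, lexicon$heads))
  structure(list(lexicon_name = lexicon$name, indicator = ind,
                 m = sum(ind)), class = "rc_sentence_vector")
}

#' Cosine similarity of a sentence vector with its trigger list
#'
#' The trigger list is represented as the uniform unit vector y over its n
#' entries; the sentence is the binary indicator x. The score is the inner
#' product x.y / (||x|| ||y||), which for binary x with m ones over n
#' dimensions equals sqrt(m/n); zero when the sentence matches nothing.
#'
#' @param x an `rc_sentence_vector` built against `lexicon`.
#' @param lexicon the `rc_lexicon` the vector was built against.
#' @return similarity score in `[0, 1]`.
#' @export
cosine_similarity <- function(x, lexicon) {
  n <- lexicon$size_n
  if (length(x$indicator) != n)
    stop("sentence vector dimension (", length(x$indicator),
         ") does not match lexicon size (", n, ")")
  if (x$m == 0L) return(0)
  y <- rep(1 / sqrt(n), n)
  sum(x$indicator * y) / sqrt(sum(x$indicator^2))
}

#' Sentence-filter configuration
#'
#' Defaults are the corpus-construction thresholds: cosine similarity to
#' the "regulate" list must exceed 0.1, similarity to the rate-change
#' (temporal) list must exceed 0.15, and the sentence must contain at
#' least two noun-tagged gene mentions. Setting both thresholds to 0
#' reproduces the looser "score above zero in both" pre-filter stage.
#'
#' @param theta_regulate threshold in `[0,1]` for the regulate score.
#' @param theta_temporal threshold in `[0,1]` for the rate-change score.
#' @param min_noun_genes minimum count of noun-tagged gene mentions.
#' @return object of class `rc_filter_config`.
#' @export
filter_config <- function(theta_regulate = 0.1, theta_temporal = 0.15,
                          min_noun_genes = 2L) {
  stopifnot(theta_regulate >= 0, theta_regulate <= 1,
            theta_temporal >= 0, theta_temporal <= 1,
            min_noun_genes >= 0)
  structure(list(theta_regulate = theta_regulate,
                 theta_temporal = theta_temporal,
                 min_noun_genes = as.integer(min_noun_genes)),
            class = "rc_filter_config")
}

# A gene mention counts as noun-tagged when any of its covered tokens
# carries an NN-prefixed tag.
count_noun_genes <- function(sentence) {
  gm <- sentence$gene_mentions
  if (is.null(gm) || nrow(gm) == 0L) return(0L)
  sum(vapply(seq_len(nrow(gm)), function(i) {
    any(startsWith(sentence$tokens$pos[gm$start[i]:gm$end[i]], "NN"))
  }, logical(1)))
}

#' Apply the three corpus-inclusion conditions to a sentence
#'
#' A sentence passes when (i) it has at least `min_noun_genes` noun-tagged
#' gene mentions, (ii) its regulate-lexicon cosine score strictly exceeds
#' `theta_regulate`, and (iii) its rate-change-lexicon score strictly
#' exceeds `theta_temporal`.
#'
#' @param sentence a tagged, gene-annotated, normalized `rc_sentence`.
#' @param regulate_lexicon,temporal_lexicon `rc_lexicon` objects.
#' @param config an [filter_config()].
#' @return list with `pass` (logical), `regulate_score`, `temporal_score`
#'   and `noun_gene_count`.
#' @export
passes_filters <- function(sentence, regulate_lexicon, temporal_lexicon,
                           config = filter_config()) {
  rs <- cosine_similarity(sentence_vector(sentence, regulate_lexicon),
                          regulate_lexicon)
  ts <- cosine_similarity(sentence_vector(sentence, temporal_lexicon),
                          temporal_lexicon)
  ng <- count_noun_genes(sentence)
  list(pass = ng >= config$min_noun_genes &&
         rs > config$theta_regulate && ts > config$theta_temporal,
       regulate_score = rs, temporal_score = ts, noun_gene_count = ng)
}

#' Filter a set of abstracts down to candidate sentences
#'
#' Preprocesses every abstract and applies [passes_filters()] to each
#' sentence, in stable (pmid, sentence index) order.
#'
#' @param abstracts list of `rc_abstract` objects.
#' @param resources resource list as from [load_default_resources()] (uses
#'   the lexicons, gene dictionary and normalization map).
#' @param config an [filter_config()].
#' @return list with `sentences` (annotated `rc_sentence`s that passed)
#'   and `report` (data.frame: pmid, sent_index, reg_score, temp_score,
#'   noun_genes, pass — one row per input sentence).
#' @export
filter_corpus <- function(abstracts, resources = load_default_resources(),
                          config = filter_config()) {
  rows <- list(); kept <- list()
  for (ab in abstracts) {
    for (s in preprocess_abstract(ab, resources$gene_dict, resources$norm_dict)) {
      res <- passes_filters(s, resources$regulate_lexicon,
                            resources$ratechange_lexicon, config)
      rows[[length(rows) + 1L]] <- data.frame(
        pmid = s$pmid, sent_index = s$index,
        reg_score = res$regulate_score, temp_score = res$temporal_score,
        noun_genes = res$noun_gene_count, pass = res$pass,
        stringsAsFactors = FALSE)
      if (res$pass) kept[[length(kept) + 1L]] <- s
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pmid = character(0), sent_index = integer(0),
               reg_score = numeric(0), temp_score = numeric(0),
               noun_genes = integer(0), pass = logical(0))
  list(sentences = kept, report = report)
}
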