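# Ontology-driven feature families over dependency parses, with the
# post-processing collapse (generic dependency types, binned path
# lengths), plus baseline feature modes.

FEATURE_MODES <- c("combined", "original_combined", "all_rules", "baseline_ace")

# Token indices treated as gene anchors: the first covered token of each
# recognized mention.
gene_anchor_indices <- function(sentence) {
  gm <- sentence$gene_mentions
  if (is.null(gm) || nrow(gm) == 0L) return(integer(0))
  unique(gm$start)
}

keyword_token_indices <- function(sentence, keywords) {
  which(sentence$tokens$normalized %in% keywords & !sentence$tokens$is_gene)
}

#' Keyword-tag features
#'
#' One binary feature `kw|<head>|<tag>` per occurrence of an ontology
#' keyword among the sentence's normalized tokens, combined with the
#' token's POS tag (set semantics: duplicates collapse).
#'
#' @param sentence a tagged, normalized `rc_sentence`.
#' @param keywords character vector of normalized keyword unigrams (see
#'   [ontology_keywords()]).
#' @return character vector of feature keys.
#' @export
extract_keyword_tag <- function(sentence, keywords) {
  idx <- keyword_token_indices(sentence, keywords)
  if (!length(idx)) return(character(0))
  sort(unique(paste("kw", sentence$tokens$normalized[idx],
                    sentence$tokens$pos[idx], sep = "|")))
}

#' Word-relation-word features along gene-keyword shortest paths
#'
#' For every gene-mention/keyword token pair, walks the shortest
#' dependency path and emits `wrw|<w1>|<reltype>|<w2>` for each
#' consecutive token pair, with words normalized. With
#' `generalize = TRUE` (the post-processing setting) dependency types are
#' collapsed to their generic class via `dep_map`.
#'
#' @param parse an `rc_parse` for the sentence.
#' @param sentence a normalized `rc_sentence` with genes recognized.
#' @param keywords normalized keyword unigrams.
#' @param dep_map generalization map from [read_dep_type_map()].
#' @param generalize collapse dependency types to generic classes?
#' @return character vector of feature keys.
#' @export
extract_word_relation_word <- function(parse, sentence, keywords,
                                       dep_map = NULL, generalize = TRUE) {
  genes <- gene_anchor_indices(sentence)
  kws <- keyword_token_indices(sentence, keywords)
  if (!length(genes) || !length(kws)) return(character(0))
  feats <- character(0)
  norm <- sentence$tokens$normalized
  for (g in genes) {
    for (k in kws) {
      path <- shortest_dependency_path(parse, g, k)
      if (path$length == 0L) next
      type <- path$edges$type
      if (generalize) {
        if (is.null(dep_map)) stop("generalize = TRUE needs a dep_map")
        type <- generalize_dep_type(type, dep_map)
      }
      feats <- c(feats, paste("wrw", norm[path$edges$from], type,
                              norm[path$edges$to], sep = "|"))
    }
  }
  sort(unique(feats))
}

#' Gene-keyword-distance features
#'
#' One feature per gene-mention/keyword pair recording the length of
#' their shortest dependency path: `gkd|genename|<keyword>|<bin>` with the
#' near/moderate/far bins (post-processing), or the raw integer length
#' when `binned = FALSE`.
#'
#' @inheritParams extract_word_relation_word
#' @param binned use the nominal near/moderate/far bins?
#' @return character vector of feature keys.
#' @export
extract_gene_keyword_distance <- function(parse, sentence, keywords,
                                          binned = TRUE) {
  genes <- gene_anchor_indices(sentence)
  kws <- keyword_token_indices(sentence, keywords)
  if (!length(genes) || !length(kws)) return(character(0))
  feats <- character(0)
  norm <- sentence$tokens$normalized
  for (g in genes) {
    for (k in kws) {
      len <- shortest_dependency_path(parse, g, k)$length
      d <- if (binned) path_bin(len) else as.character(len)
      feats <- c(feats, paste("gkd", "genename", norm[k], d, sep = "|"))
    }
  }
  sort(unique(feats))
}

# Baseline bag-of-words + parse-path features in the spirit of the ACE
# relation-extraction feature sets: all normalized words strictly between
# the outermost entity mentions, the dependency-type sequence along each
# gene-gene path, and a flag for a trigger word on that path. This is an
# approximation of the classical inventory, documented as such.
extract_baseline_ace <- function(parse, sentence, trigger_words) {
  gm <- sentence$gene_mentions
  norm <- sentence$tokens$normalized
  feats <- character(0)
  if (!is.null(gm) && nrow(gm) >= 2L) {
    lo <- min(gm$start); hi <- max(gm$end)
    if (hi - lo > 1L) {
      between <- norm[(lo + 1L):(hi - 1L)]
      between <- between[grepl("^[a-z0-9]+$", between) & between != "genename"]
      feats <- c(feats, paste0("bow|", unique(between)))
    }
    anchors <- unique(gm$start)
    for (i in seq_along(anchors)) {
      for (j in seq_along(anchors)) {
        if (j <= i) next
        path <- shortest_dependency_path(parse, anchors[i], anchors[j])
        feats <- c(feats, paste0("ppath|", paste(path$edges$type, collapse = "-")))
        on_path <- norm[path$nodes]
        if (any(on_path %in% trigger_words)) feats <- c(feats, "ptrig|1")
      }
    }
  }
  sort(unique(feats))
}

#' Build the feature vector for one sentence
#'
#' Modes:
#' \describe{
#'   \item{combined}{all three ontology-driven families with
#'     post-processing (generic dependency types, binned path lengths).}
#'   \item{original_combined}{the same families without post-processing
#'     (specific dependency types, raw integer path lengths).}
#'   \item{all_rules}{one binary feature per firing ontology pattern,
#'     from both the rate-change and the negative ontology.}
#'   \item{baseline_ace}{bag-of-words between entity mentions plus
#'     parse-path features (classical relation-extraction baseline).}
#' }
#'
#' @param sentence a tagged, gene-annotated, normalized `rc_sentence`.
#' @param parse an `rc_parse`; when `NULL`, the sentence's own `parse`
#'   element is used, falling back to [chain_parse()].
#' @param mode one of `"combined"`, `"original_combined"`, `"all_rules"`,
#'   `"baseline_ace"`.
#' @param resources resource list (ontologies, dependency-type map,
#'   lexicons) as from [load_default_resources()].
#' @return object of class `rc_features`: list with sorted unique `keys`
#'   and `mode`.
#' @export
featurize <- function(sentence, parse = NULL,
                      mode = c("combined", "original_combined",
                               "all_rules", "baseline_ace"),
                      resources = load_default_resources()) {
  mode <- match.arg(mode)
  parse <- parse %||% sentence$parse %||% chain_parse(nrow(sentence$tokens))
  pos_onto <- resources$ontology_positive
  neg_onto <- resources$ontology_negative
  keywords <- ontology_keywords(pos_onto, neg_onto)
  keys <- switch(mode,
    combined = c(
      extract_keyword_tag(sentence, keywords),
      extract_word_relation_word(parse, sentence, keywords,
                                 dep_map = resources$dep_type_map,
                                 generalize = TRUE),
      extract_gene_keyword_distance(parse, sentence, keywords, binned = TRUE)),
    original_combined = c(
      extract_keyword_tag(sentence, keywords),
      extract_word_relation_word(parse, sentence, keywords, generalize = FALSE),
      extract_gene_keyword_distance(parse, sentence, keywords, binned = FALSE)),
    all_rules = {
      pos_ids <- match_pattern_ids(sentence, pos_onto)
      neg_ids <- match_pattern_ids(sentence, neg_onto)
      c(if (length(pos_ids))
          paste0("rule|pos|", vapply(pos_onto$patterns[pos_ids], `[[`, "", "node_id"),
                 "|", pos_ids),
        if (length(neg_ids))
          paste0("rule|neg|", vapply(neg_onto$patterns[neg_ids], `[[`, "", "node_id"),
                 "|", neg_ids))
    },
    baseline_ace = extract_baseline_ace(
      parse, sentence,
      trigger_words = unique(c(resources$regulate_lexicon$heads,
                               resources$ratechange_lexicon$heads)))
  )
  structure(list(keys = sort(unique(keys)), mode = mode), class = "rc_features")
}

#' @export
print.rc_features <- function(x, ...) {
  cat("<rc_features (", x$mode, "): ", length(x$keys), " features>\n", sep = "")
  invisible(x)
}

#' Assemble a binary feature matrix from per-sentence feature vectors
#'
#' @param feature_list list of `rc_features` (or plain character vectors
#'   of feature keys).
#' @return integer 0/1 matrix, one row per sentence, columns the sorted
#'   union of feature keys.
#' @export
feature_matrix <- function(feature_list) {
  keysets <- lapply(feature_list, function(f)
    if (inherits(f, "rc_features")) f$keys else as.character(f))
  all_keys <- sort(unique(unlist(keysets)))
  m <- matrix(0L, nrow = length(keysets), ncol = length(all_keys),
              dimnames = list(NULL, all_keys))
  for (i in seq_along(keysets)) m[i, keysets[[i]]] <- 1L
  m
}

#' Write sparse feature vectors as TSV
#'
#' Two columns: sentence id and the space-joined sorted feature keys.
#'
#' @param ids character vector of sentence ids.
#' @param feature_list list of `rc_features` or key vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(ids, feature_list, path) {
  keys <- vapply(feature_list, function(f)
    paste(if (inherits(f, "rc_features")) f$keys else sort(unique(f)),
          collapse = " "), character(1))
  utils::write.table(data.frame(id = ids, features = keys, stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sparse feature vectors from TSV
#'
#' Inverse of [write_features_tsv()].
#'
#' @param path TSV path.
#' @return list with `ids` and `features` (list of key vectors).
#' @export
read_features_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  feats <- lapply(df$features, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, " ", fixed = TRUE)[[1]]
  })
  list(ids = df$id, features = feats)
}

#' Write a feature matrix in attribute-relation text format
#'
#' Minimal ARFF writer for interoperability with external tree learners:
#' every feature is a `{0,1}` nominal attribute plus a final nominal
#' `class` attribute.
#'
#' @param m binary feature matrix from [feature_matrix()].
#' @param labels character vector of class labels, one per row.
#' @param path output path.
#' @param relation relation name.
#' @return `path`, invisibly.
#' @export
write_features_arff <- function(m, labels, path, relation = "ratechange") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@RELATION ", relation), con)
  for (k in colnames(m)) {
    safe <- gsub("[^A-Za-z0-9_|]", "_", k)
    writeLines(paste0("@ATTRIBUTE '", safe, "' {0,1}"), con)
  }
  writeLines(paste0("@ATTRIBUTE class {", paste(sort(unique(labels)),
                                                collapse = ","), "}"), con)
  writeLines("@DATA", con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(m[i, ], labels[i]), collapse = ","), con)
  }
  invisible(path)
}
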