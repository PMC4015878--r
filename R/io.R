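# Corpus TSV readers/writers and the reference evaluation table.

VALID_LABELS <- c("positive", "negative")
VALID_SUBTYPES <- c("direct", "indirect_I", "indirect_II", "n/a")

#' Read an annotated corpus TSV
#'
#' Required header columns: `pmid`, `sentence_index`, `text`; optional
#' `label` (`positive`/`negative`) and `evidence_subtype`. Malformed rows
#' are reported with their line numbers; duplicate (pmid, sentence_index)
#' keys and unknown labels are errors.
#'
#' @param path TSV path (UTF-8, header row mandatory).
#' @return data.frame of validated corpus records.
#' @export
read_corpus <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  required <- c("pmid", "sentence_index", "text")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("corpus file lacks required column(s): ", paste(missing, collapse = ", "))
  lineno <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_text <- !nzchar(trimws(df$text))
  if (any(bad_text))
    stop("empty sentence text at line(s) ", paste(lineno[bad_text], collapse = ", "))
  df$sentence_index <- suppressWarnings(as.integer(df$sentence_index))
  bad_idx <- is.na(df$sentence_index)
  if (any(bad_idx))
    stop("non-integer sentence_index at line(s) ", paste(lineno[bad_idx], collapse = ", "))
  key <- paste(df$pmid, df$sentence_index)
  if (anyDuplicated(key)) {
    dup <- lineno[duplicated(key)]
    stop("duplicate (pmid, sentence_index) key at line(s) ", paste(dup, collapse = ", "))
  }
  if ("label" %in% names(df)) {
    bad <- !is.na(df$label) & nzchar(df$label) & !df$label %in% VALID_LABELS
    if (any(bad))
      stop("unknown label '", df$label[bad][1L], "' at line ", lineno[bad][1L],
           " (expected positive/negative)")
  }
  if ("evidence_subtype" %in% names(df)) {
    bad <- !is.na(df$evidence_subtype) & nzchar(df$evidence_subtype) &
      !df$evidence_subtype %in% VALID_SUBTYPES
    if (any(bad))
      stop("unknown evidence_subtype '", df$evidence_subtype[bad][1L],
           "' at line ", lineno[bad][1L])
  }
  df
}

#' Write a corpus TSV
#'
#' Inverse of [read_corpus()]. TSV, UTF-8, header row; sentences may
#' contain commas, so TSV is used throughout.
#'
#' @param df corpus data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Reference evaluation results for the original annotated corpus
#'
#' The confusion counts and metric percentages reported for the original
#' 1309-sentence event-detection corpus and its 357-sentence
#' direct-evidence subset, bundled so the metric arithmetic can be checked
#' against an independent source. Columns: `task`, `method`, `tp`, `fp`,
#' `fn`, `tn`, `precision`, `recall`, `f1`, `accuracy`.
#'
#' @return data.frame of reference rows.
#' @export
reference_results <- function() {
  utils::read.delim(rc_resource("reference_results.tsv"),
                    stringsAsFactors = FALSE)
}

#' Convert annotated sentences to corpus records
#'
#' @param sentences list of `rc_sentence` objects (with optional `label`
#'   and `subtype` fields).
#' @return corpus data.frame compatible with [write_corpus()].
#' @export
sentences_to_corpus <- function(sentences) {
  do.call(rbind, lapply(sentences, function(s) data.frame(
    pmid = s$pmid, sentence_index = s$index, text = s$raw,
    label = s$label %||% "", evidence_subtype = s$subtype %||% "",
    stringsAsFactors = FALSE)))
}

#' Annotate corpus records into sentence objects
#'
#' @param df corpus data.frame from [read_corpus()].
#' @param resources resource list.
#' @return list of annotated `rc_sentence` objects (with toy chain parses).
#' @export
corpus_to_sentences <- function(df, resources = load_default_resources()) {
  lapply(seq_len(nrow(df)), function(i) {
    s <- structure(list(pmid = df$pmid[i], index = df$sentence_index[i],
                        raw = df$text[i], tokens = NULL,
                        gene_mentions = NULL, parse = NULL),
                   class = "rc_sentence")
    s <- preprocess_sentence(s, resources$gene_dict, resources$norm_dict)
    s$parse <- typed_chain_parse(nrow(s$tokens))
    if ("label" %in% names(df) && nzchar(df$label[i])) s$label <- df$label[i]
    if ("evidence_subtype" %in% names(df) && nzchar(df$evidence_subtype[i]))
      s$subtype <- df$evidence_subtype[i]
    s
  })
}
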