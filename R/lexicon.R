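# Trigger lexicons, rate-direction classes and normalization/gene dictionaries.

#' Read a trigger-word lexicon
#'
#' A lexicon file has one entry per line: either a bare word/phrase or
#' `surface<TAB>head` when the surface form should be recorded alongside a
#' normalized head form. Entries are lower-cased; duplicates after
#' normalization are collapsed with a warning. Multi-word entries (e.g.
#' "shut down") are kept as space-separated units and later matched as
#' contiguous token n-grams.
#'
#' @param path path to a UTF-8 lexicon file.
#' @param name identifier for the lexicon (defaults to the file stem).
#' @return an object of class `rc_lexicon` with fields `name`, `entries`
#'   (data.frame of `surface`, `head`), `heads` (unique normalized heads,
#'   the vector-space dimensions) and `size_n`.
#' @export
read_lexicon <- function(path, name = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty lexicon: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  surface <- tolower(vapply(parts, `[`, "", 1L))
  head <- tolower(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L], ""))
  dup <- duplicated(head)
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate normalized entr",
            if (sum(dup) == 1L) "y" else "ies", " in lexicon ", path)
  }
  entries <- data.frame(surface = surface[!dup], head = head[!dup],
                        stringsAsFactors = FALSE)
  structure(
    list(name = name %||% sub("\\.[^.]*$", "", basename(path)),
         entries = entries, heads = entries$head, size_n = nrow(entries)),
    class = "rc_lexicon"
  )
}

#' @export
print.rc_lexicon <- function(x, ...) {
  cat("<rc_lexicon '", x$name, "': ", x$size_n, " entries>\n", sep = "")
  invisible(x)
}

#' Build a lexicon from a character vector
#'
#' @param words character vector of entries (lower-cased, deduplicated).
#' @param name lexicon identifier.
#' @return an `rc_lexicon`.
#' @export
as_lexicon <- function(words, name = "lexicon") {
  words <- unique(tolower(trimws(words)))
  words <- words[nzchar(words)]
  if (length(words) == 0L) stop("empty lexicon")
  structure(
    list(name = name,
         entries = data.frame(surface = words, head = words, stringsAsFactors = FALSE),
         heads = words, size_n = length(words)),
    class = "rc_lexicon"
  )
}

#' Read the rate-direction trigger classes
#'
#' The three disjoint classes of rate-change trigger words: `Quicken`
#' (speed-ups), `Delay` (slow-downs) and `Change` (other rate or duration
#' alterations).
#'
#' @param path TSV with header columns `class` and `word`.
#' @return data.frame with columns `class`, `word`.
#' @export
read_rate_directions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "word") %in% names(df)))
  df$word <- tolower(df$word)
  bad <- setdiff(unique(df$class), c("Quicken", "Delay", "Change"))
  if (length(bad)) stop("unknown rate-direction class: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$word)) stop("rate-direction classes must be disjoint")
  df
}

#' Classify the rate direction of a trigger word
#'
#' @param word a normalized token or multi-word unit.
#' @param directions data.frame from [read_rate_directions()].
#' @return `"Quicken"`, `"Delay"`, `"Change"`, or `NA_character_` when the
#'   word belongs to no class.
#' @export
classify_rate_direction <- function(word, directions) {
  hit <- match(tolower(word), directions$word)
  ifelse(is.na(hit), NA_character_, directions$class[hit])
}

#' Read the word normalization dictionary
#'
#' Each row lists a head word in the first column followed by its variant
#' forms, TAB-separated. The returned map sends each variant (and each head,
#' so normalization is idempotent) to its head.
#'
#' @param path TSV dictionary path.
#' @return named character vector: `map[variant] == head`.
#' @export
read_norm_dict <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  map <- character(0)
  for (ln in lines) {
    parts <- tolower(trimws(strsplit(ln, "\t", fixed = TRUE)[[1]]))
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) next
    head <- parts[1L]
    for (v in parts) {
      if (v %in% names(map) && map[[v]] != head) {
        warning("normalization dictionary maps '", v, "' to both '",
                map[[v]], "' and '", head, "'; keeping the first")
        next
      }
      map[v] <- head
    }
  }
  map
}

#' Read a gene synonym dictionary
#'
#' TSV with header; first column the canonical gene identifier, remaining
#' columns synonyms. Lookup is case-insensitive.
#'
#' @param path dictionary path.
#' @return an object of class `rc_gene_dict`: a list with `map` (named
#'   character vector synonym -> canonical id, synonyms upper-cased) and
#'   `max_len` (maximum token length of a synonym).
#' @export
read_gene_dict <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[-1L]  # header
  map <- character(0)
  for (ln in lines) {
    parts <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    id <- parts[1L]
    map[toupper(id)] <- id  # canonical id always matches itself
    for (syn in parts[-1L]) map[toupper(syn)] <- id
  }
  max_len <- max(lengths(strsplit(names(map), "\\s+")))
  structure(list(map = map, max_len = max_len), class = "rc_gene_dict")
}

#' @export
print.rc_gene_dict <- function(x, ...) {
  cat("<rc_gene_dict: ", length(unique(x$map)), " genes, ",
      length(x$map), " synonyms>\n", sep = "")
  invisible(x)
}

# Match lexicon/pattern entries against a normalized token sequence.
# Multi-word entries match as contiguous n-grams. Returns a logical vector
# parallel to `entries`.
match_entries <- function(norm_tokens, entries) {
  vapply(entries, function(e) {
    words <- strsplit(e, " ", fixed = TRUE)[[1]]
    k <- length(words)
    if (k == 1L) return(e %in% norm_tokens)
    n <- length(norm_tokens)
    if (n < k) return(FALSE)
    for (i in seq_len(n - k + 1L)) {
      if (all(norm_tokens[i:(i + k - 1L)] == words)) return(TRUE)
    }
    FALSE
  }, logical(1))
}
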