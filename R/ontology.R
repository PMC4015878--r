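# Gene-regulation ontologies: typed nodes/relations, transitive inference
# and polarized textual patterns.

RELATION_TYPES <- c("is_a", "part_of", "result_from")

#' Construct an ontology object
#'
#' An ontology holds event-class nodes, typed relations among them
#' (`is_a`, `part_of`, `result_from`) and textual patterns: per-node sets
#' of required normalized keywords whose joint occurrence in a sentence
#' signals the node's event class. Polarity marks the ontology as positive
#' (rate-change evidence) or negative (veto contexts).
#'
#' @param nodes data.frame with columns `id`, `label`, `count` (count may
#'   be `NA` when the class has no recorded instance tally).
#' @param relations data.frame with columns `subject`, `relation`, `object`.
#' @param patterns list of lists, each with `node_id` and `keywords`
#'   (nonempty character vector of normalized head words/phrases).
#' @param name ontology identifier.
#' @param polarity `"rate_change"` or `"negative"`.
#' @return an object of class `rc_ontology`.
#' @export
ontology <- function(nodes, relations, patterns, name = "ontology",
                     polarity = c("rate_change", "negative")) {
  polarity <- match.arg(polarity)
  if (anyDuplicated(nodes$id)) stop("ontology node ids must be unique")
  if (nrow(relations)) {
    bad <- setdiff(unique(relations$relation), RELATION_TYPES)
    if (length(bad)) stop("unknown relation type: ", paste(bad, collapse = ", "))
    if (any(relations$subject == relations$object))
      stop("asserted relations must connect distinct nodes")
    missing <- setdiff(c(relations$subject, relations$object), nodes$id)
    if (length(missing)) stop("relation references unknown node: ",
                              paste(missing, collapse = ", "))
  }
  for (p in patterns) {
    if (is.null(p$node_id) || !p$node_id %in% nodes$id)
      stop("pattern references unknown node id")
    if (length(p$keywords) == 0L) stop("pattern keyword set must be nonempty")
  }
  structure(list(name = name, polarity = polarity, nodes = nodes,
                 relations = relations, patterns = patterns),
            class = "rc_ontology")
}

#' @export
print.rc_ontology <- function(x, ...) {
  cat("<rc_ontology '", x$name, "' (", x$polarity, "): ",
      nrow(x$nodes), " nodes, ", nrow(x$relations), " relations, ",
      length(x$patterns), " patterns>\n", sep = "")
  invisible(x)
}

#' Read an ontology from its JSON serialization
#'
#' The JSON layout is `{name, polarity, nodes:[{id,label,count}],
#' relations:[{subject,relation,object}], patterns:[{node_id,keywords}]}`.
#'
#' @param path JSON file path.
#' @return an `rc_ontology`.
#' @export
read_ontology <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nodes <- data.frame(
    id = vapply(obj$nodes, `[[`, "", "id"),
    label = vapply(obj$nodes, `[[`, "", "label"),
    count = vapply(obj$nodes, function(n) {
      if (is.null(n$count)) NA_integer_ else as.integer(n$count)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  relations <- data.frame(
    subject = vapply(obj$relations, `[[`, "", "subject"),
    relation = vapply(obj$relations, `[[`, "", "relation"),
    object = vapply(obj$relations, `[[`, "", "object"),
    stringsAsFactors = FALSE
  )
  patterns <- lapply(obj$patterns, function(p) {
    list(node_id = p$node_id, keywords = tolower(unlist(p$keywords)))
  })
  ontology(nodes, relations, patterns,
           name = obj$name %||% sub("\\.json$", "", basename(path)),
           polarity = obj$polarity %||% "rate_change")
}

#' Write an ontology to JSON
#'
#' Inverse of [read_ontology()].
#'
#' @param onto an `rc_ontology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(onto, path) {
  obj <- list(
    name = onto$name, polarity = onto$polarity,
    nodes = lapply(seq_len(nrow(onto$nodes)), function(i) {
      list(id = onto$nodes$id[i], label = onto$nodes$label[i],
           count = if (is.na(onto$nodes$count[i])) NULL else onto$nodes$count[i])
    }),
    relations = lapply(seq_len(nrow(onto$relations)), function(i) {
      as.list(onto$relations[i, c("subject", "relation", "object")])
    }),
    patterns = lapply(onto$patterns, function(p)
      list(node_id = p$node_id, keywords = as.list(p$keywords)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

# Composition table for typed relations: compose_relation(r1, r2) is the
# inferred type of A -r3-> C given A -r1-> B -r2-> C, or NA when the pair
# composes to nothing.
compose_relation <- function(r1, r2) {
  if (r2 == "is_a") return(r1)
  if (r1 == "is_a") return(r2)
  if (r1 == "part_of" && r2 == "result_from") return("result_from")
  if (r1 == "result_from" && r2 == "part_of") return("result_from")
  if (r1 == "part_of" && r2 == "part_of") return("part_of")
  NA_character_
}

#' Transitive closure of typed ontology relations
#'
#' Computes the least fixed point of the asserted relation set under the
#' composition rules: for any relation r, `r o is_a -> r` and
#' `is_a o r -> r`; `part_of o result_from -> result_from`;
#' `result_from o part_of -> result_from`; `part_of o part_of -> part_of`.
#' Pairs outside the table (e.g. `result_from o result_from`) infer
#' nothing. A cycle that infers a reflexive `is_a` edge is retained and
#' reported via `message()`.
#'
#' @param relations data.frame with columns `subject`, `relation`, `object`.
#' @return data.frame of the same shape containing the input relations plus
#'   all inferred ones (deduplicated, ordered by subject/relation/object).
#' @export
infer_relation_closure <- function(relations) {
  if (nrow(relations) == 0L) return(relations)
  bad <- setdiff(unique(relations$relation), RELATION_TYPES)
  if (length(bad)) stop("unknown relation type: ", paste(bad, collapse = ", "))
  key <- function(df) paste(df$subject, df$relation, df$object, sep = "\r")
  rel <- unique(relations[, c("subject", "relation", "object")])
  repeat {
    seen <- key(rel)
    new <- list()
    for (i in seq_len(nrow(rel))) {
      mid <- rel$object[i]
      js <- which(rel$subject == mid)
      for (j in js) {
        r3 <- compose_relation(rel$relation[i], rel$relation[j])
        if (is.na(r3)) next
        cand <- data.frame(subject = rel$subject[i], relation = r3,
                           object = rel$object[j], stringsAsFactors = FALSE)
        if (!key(cand) %in% seen) {
          new[[length(new) + 1L]] <- cand
          seen <- c(seen, key(cand))
        }
      }
    }
    if (length(new) == 0L) break
    rel <- rbind(rel, do.call(rbind, new))
  }
  refl <- rel$subject == rel$object & rel$relation == "is_a"
  if (any(refl)) {
    message("relation closure contains reflexive is_a edge(s) (cycle): ",
            paste(unique(rel$subject[refl]), collapse = ", "))
  }
  rel <- rel[order(rel$subject, rel$relation, rel$object), , drop = FALSE]
  rownames(rel) <- NULL
  rel
}

#' Match ontology textual patterns against a sentence
#'
#' A pattern fires when every one of its required keywords occurs among the
#' sentence's normalized tokens (order-free, whole-sentence scope;
#' multi-word keywords match as contiguous token n-grams).
#'
#' @param tokens character vector of normalized tokens, or an
#'   `rc_sentence` whose tokens carry a `normalized` column.
#' @param onto an `rc_ontology`.
#' @return sorted character vector of node ids with at least one firing
#'   pattern.
#' @export
match_patterns <- function(tokens, onto) {
  tokens <- normalized_tokens(tokens)
  fired <- vapply(onto$patterns, function(p) {
    all(match_entries(tokens, p$keywords))
  }, logical(1))
  sort(unique(vapply(onto$patterns[fired], `[[`, "", "node_id")))
}

#' Which ontology patterns fire on a sentence
#'
#' Like [match_patterns()] but resolved at pattern granularity, for use as
#' rule features and for coverage analysis.
#'
#' @inheritParams match_patterns
#' @return integer indices into `onto$patterns` of the firing patterns.
#' @export
match_pattern_ids <- function(tokens, onto) {
  tokens <- normalized_tokens(tokens)
  which(vapply(onto$patterns, function(p) {
    all(match_entries(tokens, p$keywords))
  }, logical(1)))
}

# Accept either a normalized token vector or an annotated rc_sentence.
normalized_tokens <- function(x) {
  if (inherits(x, "rc_sentence")) {
    if (is.null(x$tokens) || is.null(x$tokens$normalized) ||
        anyNA(x$tokens$normalized)) {
      stop("sentence is not normalized; run normalize_sentence() first")
    }
    return(x$tokens$normalized)
  }
  as.character(x)
}

#' All unigram keywords used by an ontology's patterns
#'
#' Multi-word pattern keywords contribute their component words; used by
#' the keyword-tag feature family.
#'
#' @param ... one or more `rc_ontology` objects.
#' @return sorted unique character vector of keyword words.
#' @export
ontology_keywords <- function(...) {
  ontos <- list(...)
  kws <- unlist(lapply(ontos, function(o)
    unlist(lapply(o$patterns, `[[`, "keywords"))))
  sort(unique(unlist(strsplit(kws, " ", fixed = TRUE))))
}
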