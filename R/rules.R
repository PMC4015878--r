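# Deterministic ontology rule-based event classification.

rule_decision <- function(label, fired_pos, fired_neg, rule_name) {
  structure(list(label = label, fired_positive_nodes = fired_pos,
                 fired_negative_nodes = fired_neg, rule_name = rule_name),
            class = "rc_rule_decision")
}

#' @export
print.rc_rule_decision <- function(x, ...) {
  cat("<", x$rule_name, " rule: ", x$label, ">",
      if (length(x$fired_positive_nodes))
        paste0("\n  + ", paste(x$fired_positive_nodes, collapse = ", ")),
      if (length(x$fired_negative_nodes))
        paste0("\n  - ", paste(x$fired_negative_nodes, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Regulation-based rule
#'
#' A sentence is a positive instance when it contains at least one
#' sub-event of the transcription rate-change ontology, i.e. at least one
#' of the ontology's textual patterns fires on its normalized tokens.
#'
#' @param sentence normalized `rc_sentence` or normalized token vector.
#' @param pos_ontology the rate-change `rc_ontology`.
#' @return an `rc_rule_decision` with fields `label`
#'   (`"positive"`/`"negative"`), `fired_positive_nodes`,
#'   `fired_negative_nodes` (empty here) and `rule_name`.
#' @export
classify_regulation_rule <- function(sentence, pos_ontology) {
  fired <- match_patterns(sentence, pos_ontology)
  rule_decision(if (length(fired)) "positive" else "negative",
                fired, character(0), "regulation_based")
}

#' Combined rule: rate-change patterns with negative-ontology veto
#'
#' Positive when at least one rate-change pattern fires and no negative
#' pattern fires; negative when a negative pattern also fires (the veto is
#' unconditional) or when no rate-change pattern fires.
#'
#' @inheritParams classify_regulation_rule
#' @param neg_ontology the negative (veto) `rc_ontology`.
#' @return an `rc_rule_decision`.
#' @export
classify_combined_rule <- function(sentence, pos_ontology, neg_ontology) {
  fired_pos <- match_patterns(sentence, pos_ontology)
  fired_neg <- match_patterns(sentence, neg_ontology)
  label <- if (length(fired_pos) && !length(fired_neg)) "positive" else "negative"
  rule_decision(label, fired_pos, fired_neg, "combined")
}

#' Classify a corpus of sentences with a deterministic rule
#'
#' @param sentences list of normalized `rc_sentence` objects (or of
#'   normalized token vectors).
#' @param pos_ontology,neg_ontology ontologies; `neg_ontology` is ignored
#'   for `rule = "regulation"`.
#' @param rule `"regulation"` or `"combined"`.
#' @return data.frame with one row per sentence: `pmid`, `sent_index`,
#'   `label`, and audit columns `fired_positive` / `fired_negative`
#'   (comma-joined node ids).
#' @export
classify_corpus <- function(sentences, pos_ontology, neg_ontology = NULL,
                            rule = c("combined", "regulation")) {
  rule <- match.arg(rule)
  if (rule == "combined" && is.null(neg_ontology))
    stop("combined rule requires the negative ontology")
  rows <- lapply(seq_along(sentences), function(i) {
    s <- sentences[[i]]
    d <- if (rule == "combined") {
      classify_combined_rule(s, pos_ontology, neg_ontology)
    } else {
      classify_regulation_rule(s, pos_ontology)
    }
    data.frame(
      pmid = if (inherits(s, "rc_sentence")) s$pmid else as.character(i),
      sent_index = if (inherits(s, "rc_sentence")) s$index else 0L,
      label = d$label,
      fired_positive = paste(d$fired_positive_nodes, collapse = ","),
      fired_negative = paste(d$fired_negative_nodes, collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
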