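# Confusion-matrix metrics, cross-validation with a pluggable tree
# learner, and the ontology pattern coverage curve.

#' Construct a confusion matrix
#'
#' Either from four counts, or from predicted and true label vectors.
#'
#' @param tp,fp,fn,tn nonnegative counts.
#' @return object of class `rc_confusion`: list with `tp`, `fp`, `fn`,
#'   `tn`, `total`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  structure(as.list(c(counts, total = sum(counts))), class = "rc_confusion")
}

#' @rdname confusion_matrix
#' @param predicted,truth label vectors.
#' @param positive the positive-class label.
#' @export
confusion_from_labels <- function(predicted, truth, positive = "positive") {
  stopifnot(length(predicted) == length(truth))
  confusion_matrix(
    tp = sum(predicted == positive & truth == positive),
    fp = sum(predicted == positive & truth != positive),
    fn = sum(predicted != positive & truth == positive),
    tn = sum(predicted != positive & truth != positive))
}

#' @export
print.rc_confusion <- function(x, ...) {
  cat("<rc_confusion TP=", x$tp, " FP=", x$fp, " FN=", x$fn,
      " TN=", x$tn, " (n=", x$total, ")>\n", sep = "")
  invisible(x)
}

#' Precision, recall, F1 and accuracy from a confusion matrix
#'
#' All four metrics are percentages. Precision is 0 when `tp + fp = 0`,
#' recall 0 when `tp + fn = 0`, and F1 0 when `P + R = 0`; F1 is the
#' harmonic mean of the (unrounded) precision and recall. The default
#' `digits = 2` rounds half-up to match conventional table formatting;
#' `digits = NULL` returns exact values.
#'
#' @param cm an `rc_confusion` (or list with tp/fp/fn/tn).
#' @param digits decimal places for half-up rounding, or `NULL` for none.
#' @return named numeric vector `precision`, `recall`, `f1`, `accuracy`.
#' @export
compute_metrics <- function(cm, digits = 2) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix")
  P <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  R <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  A <- 100 * (tp + tn) / total
  out <- c(precision = P, recall = R, f1 = F1, accuracy = A)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Train a decision tree on binary features
#'
#' Wraps a CART learner behind a fit/predict contract. The default engine
#' is `rpart`; `engine = "greedy"` selects a small pure-R recursive
#' Gini-impurity tree useful as an independent cross-check. A
#' single-class training set yields a constant predictor with a warning.
#'
#' @param x binary 0/1 feature matrix (rows = instances).
#' @param labels character/factor vector of class labels.
#' @param engine `"rpart"` or `"greedy"`.
#' @param ... passed to `rpart::rpart` (rpart engine only).
#' @return object of class `rc_tree` with a [predict.rc_tree()] method.
#' @export
train_tree <- function(x, labels, engine = c("rpart", "greedy"), ...) {
  engine <- match.arg(engine)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2L) {
    warning("single-class training set; returning a constant predictor")
    return(structure(list(engine = "constant", label = labels[1L]),
                     class = "rc_tree"))
  }
  if (engine == "rpart") {
    df <- as.data.frame(x)
    safe <- paste0("f", seq_len(ncol(x)))
    names(df) <- safe
    df$.label <- factor(labels)
    fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                        control = rpart::rpart.control(minsplit = 2, cp = 0.01,
                                                       xval = 0), ...)
    return(structure(list(engine = "rpart", fit = fit, safe = safe,
                          keys = colnames(x)), class = "rc_tree"))
  }
  node <- grow_greedy(x, labels, depth = 0L, max_depth = 12L)
  structure(list(engine = "greedy", node = node, keys = colnames(x)),
            class = "rc_tree")
}

# Recursive Gini split on binary columns; leaves predict the majority
# class (ties break to the lexicographically smaller label).
grow_greedy <- function(x, labels, depth, max_depth) {
  majority <- names(sort(table(labels), decreasing = TRUE))[1L]
  if (length(unique(labels)) == 1L || depth >= max_depth || nrow(x) < 2L)
    return(list(leaf = TRUE, label = majority))
  gini <- function(l) {
    p <- table(l) / length(l)
    1 - sum(p^2)
  }
  n <- length(labels)
  best <- list(score = gini(labels) - 1e-9, col = NA_integer_)
  for (j in seq_len(ncol(x))) {
    on <- x[, j] == 1L
    if (!any(on) || all(on)) next
    score <- (sum(on) * gini(labels[on]) + sum(!on) * gini(labels[!on])) / n
    if (score < best$score) best <- list(score = score, col = j)
  }
  if (is.na(best$col)) return(list(leaf = TRUE, label = majority))
  on <- x[, best$col] == 1L
  list(leaf = FALSE, col = best$col,
       yes = grow_greedy(x[on, , drop = FALSE], labels[on], depth + 1L, max_depth),
       no = grow_greedy(x[!on, , drop = FALSE], labels[!on], depth + 1L, max_depth),
       label = majority)
}

#' Predict with a trained tree
#'
#' @param object an `rc_tree`.
#' @param newdata binary feature matrix with the same columns used in
#'   training (extra columns are ignored, missing ones treated as 0).
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.rc_tree <- function(object, newdata, ...) {
  if (object$engine == "constant")
    return(rep(object$label, nrow(newdata)))
  aligned <- matrix(0L, nrow = nrow(newdata), ncol = length(object$keys),
                    dimnames = list(NULL, object$keys))
  shared <- intersect(colnames(newdata), object$keys)
  aligned[, shared] <- newdata[, shared, drop = FALSE]
  if (object$engine == "rpart") {
    df <- as.data.frame(aligned)
    names(df) <- object$safe
    return(as.character(predict(object$fit, df, type = "class")))
  }
  walk <- function(node, row) {
    while (!node$leaf) node <- if (row[node$col] == 1L) node$yes else node$no
    node$label
  }
  vapply(seq_len(nrow(aligned)), function(i) walk(object$node, aligned[i, ]),
         character(1))
}

#' Cross-validation configuration
#'
#' @param k number of folds (default 10).
#' @param seed integer RNG seed for fold assignment.
#' @param stratified stratify folds by class (default TRUE)?
#' @return object of class `rc_cv_config`.
#' @export
cv_config <- function(k = 10L, seed = 7L, stratified = TRUE) {
  stopifnot(k >= 2L)
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "rc_cv_config")
}

# Deterministic fold assignment: shuffle (within class when stratified),
# then deal instances round-robin so fold sizes differ by at most one.
assign_folds <- function(labels, config) {
  n <- length(labels)
  if (config$k > n) stop("k (", config$k, ") exceeds instance count (", n, ")")
  with_seed(config$seed, {
    order_idx <- if (config$stratified) {
      unlist(lapply(sort(unique(labels)), function(cl) {
        idx <- which(labels == cl)
        idx[sample.int(length(idx))]
      }))
    } else {
      sample.int(n)
    }
    folds <- integer(n)
    folds[order_idx] <- rep_len(seq_len(config$k), n)
    folds
  })
}

#' k-fold cross-validation of a tree learner
#'
#' Folds are disjoint with union equal to the instance set; per-fold test
#' confusion matrices are summed into one aggregate, so the aggregate
#' total equals the corpus size.
#'
#' @param x binary feature matrix.
#' @param labels class labels (the positive class is `positive` for the
#'   confusion matrix).
#' @param config an [cv_config()].
#' @param positive positive-class label.
#' @param engine tree engine passed to [train_tree()].
#' @return list with `cm` (aggregate `rc_confusion`), `metrics`
#'   (from [compute_metrics()]), `folds` (assignment vector) and
#'   `per_fold` (list of per-fold confusion matrices).
#' @export
run_cv <- function(x, labels, config = cv_config(), positive = "positive",
                   engine = "rpart") {
  labels <- as.character(labels)
  folds <- assign_folds(labels, config)
  per_fold <- vector("list", config$k)
  agg <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (f in seq_len(config$k)) {
    test <- folds == f
    tree <- suppressWarnings(
      train_tree(x[!test, , drop = FALSE], labels[!test], engine = engine))
    pred <- predict(tree, x[test, , drop = FALSE])
    cm <- confusion_from_labels(pred, labels[test], positive = positive)
    per_fold[[f]] <- cm
    agg <- agg + c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
  }
  cm <- confusion_matrix(agg[["tp"]], agg[["fp"]], agg[["fn"]], agg[["tn"]])
  list(cm = cm, metrics = compute_metrics(cm), folds = folds,
       per_fold = per_fold)
}

#' Cumulative pattern coverage curve over shuffled sentence orderings
#'
#' For each random ordering of the sentences, records after each prefix
#' the fraction of ontology patterns already seen (a pattern is "seen"
#' once any sentence on which it fires has appeared); the curves are
#' averaged over `n_shuffles` orderings. Each single-shuffle curve is
#' non-decreasing and ends at the fraction of patterns that occur
#' anywhere in the corpus.
#'
#' @param sentences list of normalized `rc_sentence` objects or normalized
#'   token vectors.
#' @param onto an `rc_ontology` supplying the patterns.
#' @param n_shuffles number of random orderings to average.
#' @param seed RNG seed.
#' @return data.frame with `n_sentences` (prefix size 1..N) and `fraction`
#'   (mean cumulative fraction of patterns seen).
#' @export
coverage_curve <- function(sentences, onto, n_shuffles = 100L, seed = 7L) {
  if (length(onto$patterns) == 0L) stop("ontology has no patterns")
  n_pat <- length(onto$patterns)
  hit_sets <- lapply(sentences, match_pattern_ids, onto = onto)
  n <- length(hit_sets)
  acc <- numeric(n)
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      ord <- sample.int(n)
      seen <- logical(n_pat)
      curve <- numeric(n)
      for (i in seq_len(n)) {
        seen[hit_sets[[ord[i]]]] <- TRUE
        curve[i] <- sum(seen) / n_pat
      }
      acc <- acc + curve
    }
  })
  data.frame(n_sentences = seq_len(n), fraction = acc / n_shuffles)
}
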