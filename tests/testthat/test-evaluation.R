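test_that("confusion metrics follow the standard formulas with half-up rounding", {
  m1 <- compute_metrics(confusion_matrix(322, 158, 35, 794))
  expect_equal(unname(m1), c(67.08, 90.20, 76.94, 85.26))
  m2 <- compute_metrics(confusion_matrix(185, 122, 26, 24))
  expect_equal(unname(m2), c(60.26, 87.68, 71.43, 58.54))
  m3 <- compute_metrics(confusion_matrix(10, 0, 0, 10))
  expect_equal(unname(m3), c(100, 100, 100, 100))
  # degenerate conventions
  m4 <- compute_metrics(confusion_matrix(0, 0, 5, 5))
  expect_equal(unname(m4), c(0, 0, 0, 50))
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
  expect_error(confusion_matrix(-1, 0, 0, 1), "nonnegative")
})

test_that("confusion matrices from label vectors count the four cells", {
  pred <- c("positive", "positive", "negative", "negative", "positive")
  truth <- c("positive", "negative", "positive", "negative", "positive")
  cm <- confusion_from_labels(pred, truth)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(2L, 1L, 1L, 1L))
  expect_equal(cm$total, 5L)
})

test_that("round_half_up resolves ties upward", {
  expect_equal(round_half_up(90.205, 2), 90.21)
  expect_equal(round_half_up(76.935, 2), 76.94)
  expect_equal(round_half_up(-1.005, 2), -1.01)
})

test_that("tree training honours the fit/predict contract", {
  set.seed(1)
  x <- matrix(rbinom(200, 1, 0.5), nrow = 50,
              dimnames = list(NULL, paste0("f", 1:4)))
  labels <- ifelse(x[, 2] == 1, "positive", "negative")
  for (engine in c("rpart", "greedy")) {
    tree <- train_tree(x, labels, engine = engine)
    expect_equal(predict(tree, x), labels)
  }
  # all-identical features, mixed labels -> majority class
  x0 <- matrix(1L, nrow = 10, ncol = 2, dimnames = list(NULL, c("a", "b")))
  lab0 <- c(rep("positive", 7), rep("negative", 3))
  expect_equal(unique(predict(train_tree(x0, lab0), x0)), "positive")
  # single-class training set -> constant predictor with warning
  expect_warning(t1 <- train_tree(x0, rep("positive", 10)), "single-class")
  expect_equal(predict(t1, x0), rep("positive", 10))
})

test_that("cross-validation folds are disjoint, exhaustive and reproducible", {
  set.seed(2)
  x <- matrix(rbinom(400, 1, 0.5), nrow = 100,
              dimnames = list(NULL, paste0("f", 1:4)))
  labels <- ifelse(x[, 1] == 1, "positive", "negative")
  cfg <- cv_config(k = 10, seed = 7)
  r1 <- run_cv(x, labels, cfg)
  r2 <- run_cv(x, labels, cfg)
  expect_identical(r1$folds, r2$folds)
  expect_equal(sort(unique(r1$folds)), 1:10)
  expect_equal(r1$cm$total, 100L)
  # stratified fold sizes differ by at most one
  expect_lte(diff(range(table(r1$folds))), 1)
  # separable labels recovered perfectly
  expect_equal(unname(r1$metrics["f1"]), 100)
  # leave-one-out aggregates to the corpus size
  small <- x[1:10, ]
  lab_small <- c(rep("positive", 5), rep("negative", 5))
  loo <- run_cv(small, lab_small, cv_config(k = 10, seed = 1))
  expect_equal(loo$cm$total, 10L)
  expect_error(run_cv(small, lab_small, cv_config(k = 11, seed = 1)), "exceeds")
})

test_that("coverage curves are monotone and reach the corpus-wide fraction", {
  onto <- ontology(
    nodes = data.frame(id = paste0("n", 1:4), label = paste0("n", 1:4),
                       count = NA_integer_, stringsAsFactors = FALSE),
    relations = data.frame(subject = character(0), relation = character(0),
                           object = character(0), stringsAsFactors = FALSE),
    patterns = lapply(1:4, function(i) list(node_id = paste0("n", i),
                                            keywords = paste0("k", i))),
    name = "toy")
  # every sentence contains all patterns -> constant 1 under every shuffle
  all_in_each <- rep(list(c("k1", "k2", "k3", "k4")), 3)
  cc <- coverage_curve(all_in_each, onto, n_shuffles = 20, seed = 1)
  expect_equal(cc$fraction, rep(1, 3))
  # patterns absent from the corpus cap the curve below 1
  partial <- list("k1", "x")
  cc2 <- coverage_curve(partial, onto, n_shuffles = 20, seed = 1)
  expect_equal(cc2$fraction[2], 0.25)
  expect_true(all(diff(cc2$fraction) >= 0))
})

test_that("coverage of ten one-pattern sentences is exactly j/10 at prefix j", {
  onto <- ontology(
    nodes = data.frame(id = paste0("n", 1:10), label = paste0("n", 1:10),
                       count = NA_integer_, stringsAsFactors = FALSE),
    relations = data.frame(subject = character(0), relation = character(0),
                           object = character(0), stringsAsFactors = FALSE),
    patterns = lapply(1:10, function(i) list(node_id = paste0("n", i),
                                             keywords = paste0("k", i))),
    name = "toy")
  sentences <- lapply(1:10, function(i) paste0("k", i))
  cc <- coverage_curve(sentences, onto, n_shuffles = 50, seed = 3)
  # each sentence reveals exactly one new pattern, so every shuffle gives j/10
  expect_equal(cc$fraction, (1:10) / 10, tolerance = 1e-12)
})
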