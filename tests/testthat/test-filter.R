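test_that("sentence vectors are binary indicators over the lexicon", {
  lex <- as_lexicon(c("regulate", "induce", "repress"), "toy")
  v <- sentence_vector(c("x", "repress", "y", "repress"), lex)
  expect_equal(v$indicator, c(0L, 0L, 1L))
  expect_equal(v$m, 1L)
  expect_equal(sentence_vector(c("nothing", "matches"), lex)$indicator,
               c(0L, 0L, 0L))
})

test_that("the worked positive example matches at least two regulate triggers", {
  res <- test_resources()
  s <- fixture_sentences(resources = res)[[1]]
  v <- sentence_vector(s, res$regulate_lexicon)
  expect_gte(v$m, 2L)  # repression -> repress, induction -> induce, ...
})

test_that("cosine similarity equals the inner-product formula", {
  lex <- as_lexicon(paste0("w", 1:25), "toy")
  expect_equal(cosine_similarity(sentence_vector("none", lex), lex), 0)
  expect_equal(cosine_similarity(sentence_vector(paste0("w", 1:25), lex), lex), 1)
  expect_equal(cosine_similarity(sentence_vector("w1", lex), lex), 0.2)
  # dimension mismatch
  other <- as_lexicon(paste0("w", 1:10), "other")
  expect_error(cosine_similarity(sentence_vector("w1", lex), other), "dimension")
})

test_that("cosine similarity matches a brute-force oracle for all m <= n <= 50", {
  for (n in 1:50) {
    lex <- as_lexicon(paste0("w", seq_len(n)), "toy")
    y <- rep(1, n) / sqrt(n)
    for (m in 0:n) {
      toks <- if (m > 0) paste0("w", seq_len(m)) else "zzz"
      v <- sentence_vector(toks, lex)
      x <- v$indicator
      oracle <- if (m == 0) 0 else sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
      expect_equal(cosine_similarity(v, lex), oracle, tolerance = 1e-12)
    }
  }
})

test_that("scores are invariant under duplication of matched words", {
  res <- test_resources()
  lex <- res$ratechange_lexicon
  v1 <- sentence_vector(c("genename", "slow", "induce"), lex)
  v2 <- sentence_vector(c("genename", "slow", "slow", "slow", "induce"), lex)
  expect_equal(cosine_similarity(v1, lex), cosine_similarity(v2, lex))
})

test_that("the three inclusion conditions combine with strict thresholds", {
  # lexicons sized so scores hit the boundary exactly: sqrt(1/100) = 0.1,
  # sqrt(9/400) = 0.15
  reg <- as_lexicon(paste0("r", 1:100), "regulate")
  temp <- as_lexicon(paste0("t", 1:400), "temporal")
  two_genes <- function(extra) make_sentence(
    c("genename", "genename", extra),
    pos = c("NN", "NN", rep("NN", length(extra))),
    is_gene = c(TRUE, TRUE, rep(FALSE, length(extra))))

  boundary <- two_genes(c("r1", paste0("t", 1:9)))
  res_b <- passes_filters(boundary, reg, temp, filter_config(0.1, 0.15, 2))
  expect_equal(res_b$regulate_score, 0.1)
  expect_equal(res_b$temporal_score, 0.15)
  expect_false(res_b$pass)   # "exceeds" is strict

  # one noun gene fails condition (i) regardless of scores
  one_gene <- make_sentence(c("genename", "r1", "t1"),
                            is_gene = c(TRUE, FALSE, FALSE))
  expect_false(passes_filters(one_gene, reg, temp,
                              filter_config(0.0, 0.0, 2))$pass)

  # scores (~0.12, ~0.16) with 2 noun genes pass
  reg2 <- as_lexicon(paste0("r", 1:200), "regulate")
  temp2 <- as_lexicon(paste0("t", 1:78), "temporal")
  ok <- two_genes(c(paste0("r", 1:3), paste0("t", 1:2)))
  res_ok <- passes_filters(ok, reg2, temp2, filter_config(0.1, 0.15, 2))
  expect_true(res_ok$pass)
  expect_gt(res_ok$regulate_score, 0.1)
  expect_gt(res_ok$temporal_score, 0.15)
})

test_that("filter_corpus keeps exactly the planted qualifying sentences", {
  res <- test_resources()
  expect_length(filter_corpus(list(), res)$sentences, 0L)

  # abstracts with one qualifying sentence and one trivially disqualified one
  abstracts <- lapply(1:5, function(i) abstract(
    sprintf("A%02d", i),
    paste("MTH1 slowed repression of HXT3 expression in cells.",
          "Nothing relevant here.")))
  out <- filter_corpus(abstracts, res, filter_config(0, 0, 2))
  expect_length(out$sentences, 5L)
  expect_equal(nrow(out$report), 10L)
  expect_equal(sum(out$report$pass), 5L)
  # stable order by (pmid, index)
  expect_equal(out$report$pmid, rep(sprintf("A%02d", 1:5), each = 2))
})

test_that("the survivor set is antitone in thresholds and gene count", {
  res <- test_resources()
  corpus <- generate_corpus(generator_config(n_sentences = 40, seed = 5), res)
  survivors <- function(cfg) sum(vapply(corpus, function(s)
    passes_filters(s, res$regulate_lexicon, res$ratechange_lexicon, cfg)$pass,
    logical(1)))
  base <- survivors(filter_config(0.1, 0.15, 2))
  expect_gte(survivors(filter_config(0, 0, 2)), base)
  expect_gte(survivors(filter_config(0.1, 0.15, 0)), base)
  expect_lte(survivors(filter_config(0.5, 0.5, 2)), base)
})
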