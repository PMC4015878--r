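toy_parse_sentence <- function() {
  # MTH1 is slowed : slowed is the root, MTH1 its nsubj
  s <- make_sentence(c("genename", "is", "slow"),
                     pos = c("NN", "VBZ", "VBN"),
                     is_gene = c(TRUE, FALSE, FALSE))
  parse <- dependency_parse(
    data.frame(head = c(3L, 3L), dep = c(1L, 2L),
               type = c("nsubj", "cop"), stringsAsFactors = FALSE),
    3L, 3L)
  list(sentence = s, parse = parse)
}

test_that("dependency parse validation rejects malformed trees", {
  expect_error(dependency_parse(
    data.frame(head = 1L, dep = 1L, type = "dep"), 2L, 2L), "self-loop")
  expect_error(dependency_parse(
    data.frame(head = c(1L, 1L), dep = c(2L, 2L), type = "dep"), 2L, 1L),
    "only one head")
  expect_error(dependency_parse(
    data.frame(head = 1L, dep = 2L, type = "dep"), 3L, 1L), "connected")
})

test_that("shortest dependency paths match trivial cases", {
  p <- chain_parse(3L)
  expect_equal(shortest_dependency_path(p, 1L, 1L)$length, 0L)
  expect_equal(shortest_dependency_path(p, 1L, 3L)$length, 2L)
  expect_equal(shortest_dependency_path(p, 1L, 3L)$nodes, c(1L, 2L, 3L))
})

test_that("shortest-path lengths equal a BFS oracle on random trees", {
  set.seed(77)
  for (rep in seq_len(200)) {
    n <- sample(2:10, 1L)
    edges <- data.frame(
      head = vapply(2:n, function(k) sample.int(k - 1L, 1L), integer(1)),
      dep = 2:n, type = "dep", stringsAsFactors = FALSE)
    parse <- dependency_parse(edges, n, 1L)
    a <- sample.int(n, 1L); b <- sample.int(n, 1L)
    got <- shortest_dependency_path(parse, a, b)
    expect_equal(got$length, bfs_distance(edges, n, a, b))
    expect_equal(got$nodes[1], a)
    expect_equal(got$nodes[length(got$nodes)], b)
  }
})

test_that("path bins partition all nonnegative lengths with 3 as near", {
  expect_equal(path_bin(c(0, 2, 3)), c("near", "near", "near"))
  expect_equal(path_bin(c(4, 5, 6)), rep("moderate", 3))
  expect_equal(path_bin(c(7, 20)), c("far", "far"))
  expect_setequal(unique(path_bin(0:30)), c("near", "moderate", "far"))
})

test_that("keyword-tag features pair ontology keywords with POS tags", {
  tp <- toy_parse_sentence()
  expect_equal(extract_keyword_tag(tp$sentence, "slow"), "kw|slow|VBN")
  expect_length(extract_keyword_tag(tp$sentence, "promoter"), 0)
  # duplicates collapse
  s2 <- make_sentence(c("slow", "slow"), pos = c("VBN", "VBN"),
                      is_gene = c(FALSE, FALSE))
  expect_equal(extract_keyword_tag(s2, "slow"), "kw|slow|VBN")
})

test_that("word-relation-word features walk the gene-keyword shortest path", {
  tp <- toy_parse_sentence()
  feats <- extract_word_relation_word(tp$parse, tp$sentence, "slow",
                                      generalize = FALSE)
  expect_equal(feats, "wrw|genename|nsubj|slow")
  # generalization collapses nsubj to its subj class
  res <- test_resources()
  gen <- extract_word_relation_word(tp$parse, tp$sentence, "slow",
                                    dep_map = res$dep_type_map, generalize = TRUE)
  expect_equal(gen, "wrw|genename|subj|slow")
  # no keyword -> no features
  expect_length(extract_word_relation_word(tp$parse, tp$sentence, "promoter"), 0)
})

test_that("gene-keyword-distance features bin the path length", {
  res <- test_resources()
  s <- make_sentence(c("genename", "a", "b", "c", "d", "slow", "g", "promoter"),
                     is_gene = c(TRUE, rep(FALSE, 7)))
  parse <- chain_parse(8L)
  feats <- extract_gene_keyword_distance(parse, s, c("slow", "promoter"))
  expect_setequal(feats, c("gkd|genename|slow|moderate", "gkd|genename|promoter|far"))
  raw <- extract_gene_keyword_distance(parse, s, c("slow", "promoter"),
                                       binned = FALSE)
  expect_setequal(raw, c("gkd|genename|slow|5", "gkd|genename|promoter|7"))
})

test_that("featurize modes behave as specified on the worked examples", {
  res <- test_resources()
  fx <- fixture_sentences(resources = res)
  # all_rules on the replication-fork example includes the veto feature
  fr <- featurize(fx[[7]], mode = "all_rules", resources = res)
  expect_true(any(grepl("^rule\\|neg\\|dna_replication", fr$keys)))
  expect_true(any(grepl("^rule\\|pos\\|", fr$keys)))
  # keyword-free sentence gives an empty combined vector
  bare <- make_sentence(c("genename", "nothing", "genename"),
                        is_gene = c(TRUE, FALSE, TRUE))
  expect_length(featurize(bare, chain_parse(3L), "combined", res)$keys, 0)
  # post-processing is a pure collapse: combined count <= original count
  for (i in c(1, 3, 5)) {
    comb <- featurize(fx[[i]], mode = "combined", resources = res)
    orig <- featurize(fx[[i]], mode = "original_combined", resources = res)
    expect_lte(length(comb$keys), length(orig$keys))
    expect_gt(length(comb$keys), 0)
  }
  # determinism
  f1 <- featurize(fx[[1]], mode = "combined", resources = res)
  f2 <- featurize(fx[[1]], mode = "combined", resources = res)
  expect_identical(f1, f2)
  # baseline mode produces bag-of-words features between entities
  fb <- featurize(fx[[1]], mode = "baseline_ace", resources = res)
  expect_true(any(startsWith(fb$keys, "bow|")))
})

test_that("feature vectors round-trip through the sparse TSV format", {
  res <- test_resources()
  fx <- fixture_sentences(resources = res)[1:3]
  feats <- lapply(fx, featurize, mode = "combined", resources = res)
  ids <- vapply(fx, `[[`, "", "pmid")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(ids, feats, f)
  back <- read_features_tsv(f)
  expect_equal(back$ids, ids)
  for (i in 1:3) expect_equal(back$features[[i]], feats[[i]]$keys)
})
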