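test_that("sentence segmentation splits on boundaries but not abbreviations", {
  ab <- abstract("1", "A regulates B. C binds D.")
  sents <- segment_sentences(ab)
  expect_length(sents, 2L)
  expect_equal(sents[[1]]$raw, "A regulates B.")
  expect_equal(vapply(sents, `[[`, integer(1), "index"), c(0L, 1L))

  one <- segment_sentences(abstract("2", "S. cerevisiae grows."))
  expect_length(one, 1L)
  eg <- segment_sentences(abstract("3", "Genes act, e.g. MTH1 does. Also HXT3."))
  expect_length(eg, 2L)
})

test_that("segmented sentences reconstruct the abstract modulo whitespace", {
  for (ab in fixture_abstracts()) {
    sents <- segment_sentences(ab)
    joined <- gsub("\\s+", "", paste(vapply(sents, `[[`, "", "raw"), collapse = ""))
    expect_equal(joined, gsub("\\s+", "", ab$text))
  }
})

test_that("the PMID 16400179 abstract contains its worked-example sentence verbatim", {
  ab <- fixture_abstracts()[[1]]
  expect_equal(ab$pmid, "16400179")
  sents <- segment_sentences(ab)
  raws <- vapply(sents, `[[`, "", "raw")
  expect_true(fixture_sentences(annotate = FALSE)[[1]]$raw %in% raws)
})

test_that("tokenization and tagging give gene symbols noun-class tags", {
  s <- tokenize_and_tag(structure(list(pmid = "x", index = 0L, raw = "MTH1 is slowed"),
                                  class = "rc_sentence"))
  expect_equal(s$tokens$surface, c("MTH1", "is", "slowed"))
  expect_equal(s$tokens$pos, c("NN", "VBZ", "VBN"))
  expect_error(tokenize_and_tag(structure(list(pmid = "x", index = 0L, raw = ""),
                                          class = "rc_sentence")), "empty")
})

test_that("tagging a fixture sentence is deterministic (snapshot)", {
  s <- tokenize_and_tag(structure(
    list(pmid = "x", index = 0L,
         raw = "Deletion of CHZ1 led to reduced ubiquitination."),
    class = "rc_sentence"))
  expect_equal(s$tokens$surface,
               c("Deletion", "of", "CHZ1", "led", "to", "reduced",
                 "ubiquitination", "."))
  expect_equal(s$tokens$pos,
               c("NN", "IN", "NN", "VBN", "TO", "VBN", "NN", "."))
  # re-running yields identical output
  expect_identical(tokenize_and_tag(structure(
    list(pmid = "x", index = 0L,
         raw = "Deletion of CHZ1 led to reduced ubiquitination."),
    class = "rc_sentence"))$tokens, s$tokens)
})

test_that("gene recognition finds dictionary mentions, longest match first", {
  res <- test_resources()
  s <- fixture_sentences(annotate = FALSE)[[1]]
  s <- recognize_genes(tokenize_and_tag(s), res$gene_dict)
  gm <- s$gene_mentions
  expect_gte(nrow(gm), 3L)                       # MTH1 repeated + HXT3
  expect_setequal(unique(gm$gene_id), c("MTH1", "HXT3"))
  # spans sorted and disjoint
  expect_true(all(diff(gm$start) > 0))
  expect_true(all(gm$start[-1] > gm$end[-nrow(gm)]))

  # no dictionary, no mentions
  empty_dict <- structure(list(map = c(ZZZ9 = "ZZZ9"), max_len = 1L),
                          class = "rc_gene_dict")
  s2 <- recognize_genes(tokenize_and_tag(structure(
    list(pmid = "x", index = 0L, raw = "no genes here"), class = "rc_sentence")),
    empty_dict)
  expect_equal(nrow(s2$gene_mentions), 0L)

  # overlapping synonyms: exact token "HXT3" matches only the longer symbol
  dict <- structure(list(map = c(HXT = "HXT", HXT3 = "HXT3"), max_len = 1L),
                    class = "rc_gene_dict")
  s3 <- recognize_genes(tokenize_and_tag(structure(
    list(pmid = "x", index = 0L, raw = "HXT3 is induced"), class = "rc_sentence")),
    dict)
  expect_equal(nrow(s3$gene_mentions), 1L)
  expect_equal(s3$gene_mentions$gene_id, "HXT3")
})

test_that("normalization replaces genes with the placeholder and keywords with heads", {
  res <- test_resources()
  s <- preprocess_sentence(structure(
    list(pmid = "x", index = 0L, raw = "MTH1 degradation is slowed"),
    class = "rc_sentence"), res$gene_dict, res$norm_dict)
  expect_equal(s$tokens$normalized, c("genename", "degrade", "is", "slow"))
  # token count invariant: one normalized token per surface token
  expect_equal(nrow(s$tokens), 4L)
  # idempotence
  s2 <- normalize_sentence(s, res$norm_dict)
  expect_identical(s2$tokens$normalized, s$tokens$normalized)
})

test_that("abstract readers parse TSV and MEDLINE formats", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pmid\ttext", "11\tA regulates B.", "12\tC binds D."), tsv)
  abs1 <- read_abstracts(tsv, "tsv")
  expect_length(abs1, 2L)
  expect_equal(abs1[[2]]$pmid, "12")

  med <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PMID- 42", "TI  - A title.", "AB  - First line of the abstract",
               "      continued here.", "AU  - Someone", "", "PMID- 43",
               "AB  - Second record."), med)
  abs2 <- read_abstracts(med, "medline")
  expect_length(abs2, 2L)
  expect_equal(abs2[[1]]$pmid, "42")
  expect_match(abs2[[1]]$text, "continued here")
  expect_equal(abs2[[2]]$text, "Second record.")
})
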