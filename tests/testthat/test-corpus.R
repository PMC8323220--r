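test_that("TSV and JSON-lines corpora round-trip records and schema exactly", {
  corp <- tiny_corpus()
  for (fmt in c("tsv", "jsonl")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_corpus(corp, path, fmt)
    back <- read_corpus(path, fmt)
    expect_identical(back$text, corp$text)
    expect_identical(back$split, corp$split)
    expect_identical(corpus_schema(back)$names, corpus_schema(corp)$names)
    expect_identical(back$label, corp$label)
    unlink(path)
  }
})

test_that("jsonl round-trip preserves non-ASCII text byte-for-byte", {
  corp <- tiny_corpus()
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corp, path, "jsonl")
  back <- read_corpus(path, "jsonl")
  expect_identical(lapply(back$text, charToRaw), lapply(corp$text, charToRaw))
  unlink(path)
})

test_that("TSV reading maps sorted distinct labels to dense indices", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("年龄 > 80岁\tAge", "男、女不限\tGender"), path, useBytes = TRUE)
  corp <- read_corpus(path, "tsv")
  expect_equal(nrow(corp), 2)
  expect_identical(corpus_schema(corp)$names, c("Age", "Gender"))
  expect_identical(corp$label, c(1L, 2L))
  expect_identical(corp$split, c("train", "train"))  # default tag
  unlink(path)
})

test_that("degenerate corpus files are handled: empty file, repeated record, bad rows", {
  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(corp <- read_corpus(empty, "tsv"), "empty")
  expect_equal(nrow(corp), 0)
  expect_equal(corpus_schema(corp)$n, 0)

  rep5 <- tempfile(fileext = ".tsv")
  writeLines(rep("some criteria text\tDisease", 5), rep5)
  corp5 <- read_corpus(rep5, "tsv")
  expect_equal(nrow(corp5), 5)
  expect_true(all(corp5$label == 1L))
  expect_equal(corpus_schema(corp5)$n, 1)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("ok\tA", "\tB"), bad)
  expect_error(read_corpus(bad, "tsv"), "line 2")
  unlink(c(empty, rep5, bad))
})

test_that("TSV output rejects text containing tabs", {
  schema <- category_schema("A")
  corp <- corpus("has\ttab", 1L, "train", schema)
  expect_error(write_corpus(corp, tempfile(), "tsv"), "tab")
  # jsonl represents the same record fine
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corp, path, "jsonl")
  expect_identical(read_corpus(path, "jsonl")$text, "has\ttab")
  unlink(path)
})

test_that("class_distribution counts every schema class and sums to corpus size", {
  schema <- category_schema(c("A", "B", "C"))
  corp <- corpus(c("x1", "x2", "x3"), c(1L, 1L, 2L), "train", schema)
  expect_identical(unname(class_distribution(corp)), c(2L, 1L, 0L))
  expect_equal(sum(class_distribution(corp)), nrow(corp))
  empty <- corpus(character(), integer(), character(), schema)
  expect_identical(unname(class_distribution(empty)), c(0L, 0L, 0L))
})

test_that("generator is deterministic: identical specs give identical corpora", {
  spec <- synthetic_spec(n_classes = 6, total_samples = 300,
                         imbalance_exponent = 2, seed = 0)
  a <- generate_synthetic_corpus(spec)
  b <- generate_synthetic_corpus(spec)
  expect_identical(a$text, b$text)
  expect_identical(a$label, b$label)
  expect_identical(a$split, b$split)
  c2 <- generate_synthetic_corpus(synthetic_spec(n_classes = 6,
                                                 total_samples = 300,
                                                 imbalance_exponent = 2,
                                                 seed = 1))
  expect_false(identical(a$text, c2$text))
})

test_that("balanced no-noise spec yields ~equal classes of purely private tokens", {
  spec <- synthetic_spec(n_classes = 4, total_samples = 400,
                         imbalance_exponent = 0, noise_rate = 0,
                         class_vocab_size = 10, seed = 0)
  corp <- generate_synthetic_corpus(spec)
  counts <- unname(class_distribution(corp))
  expect_equal(sum(counts), 400)
  # multinomial around 100 each; the bound covers the max deviation over
  # the 4 cells (4 sd each), not a single cell
  expect_true(all(abs(counts - 100) <= 4 * sqrt(400 * 0.25 * 0.75)))
  # every 3-char token of a class-k text lies in class k's private pool
  toks <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s) + 2, 3))
  private <- lapply(1:4, function(k)
    critens:::token_string((k - 1) * 10 + 1:10))
  for (i in sample(nrow(corp), 50)) {
    expect_true(all(toks(corp$text[i]) %in% private[[corp$label[i]]]))
  }
})

test_that("empirical class counts track the Zipf multinomial expectation within 3 sd", {
  spec <- synthetic_spec(n_classes = 8, total_samples = 2000,
                         imbalance_exponent = 1.5, seed = 0)
  corp <- generate_synthetic_corpus(spec)
  w <- zipf_class_weights(spec)
  expected <- 2000 * w
  sds <- sqrt(2000 * w * (1 - w))
  counts <- unname(class_distribution(corp))
  expect_true(all(abs(counts - expected) <= 3 * sds))
  expect_gt(max(counts), min(counts))  # imbalance realized
})

test_that("splits are stratified: every class appears in train; tiny classes train-only", {
  corp <- generate_synthetic_corpus(synthetic_spec(n_classes = 8,
                                                   total_samples = 500,
                                                   imbalance_exponent = 2,
                                                   seed = 3))
  counts <- class_distribution(corp)
  train_counts <- class_distribution(corp, "train")
  expect_true(all(train_counts[counts > 0] > 0))
  tiny <- which(counts > 0 & counts < 3)
  for (k in tiny)
    expect_true(all(corp$split[corp$label == k] == "train"))
})

test_that("degenerate generator specs work: singleton pools and fixed lengths", {
  spec <- synthetic_spec(n_classes = 2, total_samples = 40,
                         imbalance_exponent = 0, class_vocab_size = 1,
                         shared_vocab_size = 1, noise_rate = 0,
                         length_range = c(3L, 3L), seed = 0)
  corp <- generate_synthetic_corpus(spec)
  expect_equal(nrow(corp), 40)
  expect_true(all(nchar(corp$text) == 9))  # exactly 3 pseudo-tokens
  # one private token per class: every class-k text is that token repeated
  for (k in 1:2) {
    tok <- critens:::token_string((k - 1) * 1 + 1)
    expect_true(all(corp$text[corp$label == k] == strrep(tok, 3)))
  }
})

test_that("generator refuses totals too small to stratify", {
  expect_error(generate_synthetic_corpus(
    synthetic_spec(n_classes = 10, total_samples = 5)), "stratify")
})

test_that("noise-free corpora are perfectly separated by a bag-of-tokens centroid rule", {
  corp <- generate_synthetic_corpus(synthetic_spec(
    n_classes = 8, total_samples = 800, imbalance_exponent = 1.5,
    noise_rate = 0, seed = 0))
  res <- centroid_classify(corp)
  expect_equal(mean(res$pred == res$truth), 1)
})
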