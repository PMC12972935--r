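# Corpus reading, cleaning, tokenization, severity binning and the
# stratified 8:1:1 split.

test_that("read_corpus maps JSONL and CSV records and validates ranges", {
  df <- data.frame(record_id = "r1", text = "slept badly again",
                   phq9 = 12L, gad7 = 9L, subject_id = "s1",
                   cohort = "high_school", synthetic = FALSE,
                   stringsAsFactors = FALSE)
  path <- write_tmp_jsonl(df)
  got <- read_corpus(path)
  expect_equal(got$phq9, 12L)
  expect_equal(got$gad7, 9L)
  expect_equal(got$text, "slept badly again")

  csv <- tempfile(fileext = ".csv")
  write.csv(df[, c("text", "phq9", "gad7")], csv, row.names = FALSE)
  got_csv <- read_corpus(csv)
  expect_equal(got_csv$phq9, 12L)
  expect_false(got_csv$synthetic)

  # out-of-range score names the offending record
  bad <- df; bad$phq9 <- 28L
  expect_error(read_corpus(write_tmp_jsonl(bad)), "PHQ-9.*r1")
  bad2 <- df; bad2$gad7 <- 22L
  expect_error(read_corpus(write_tmp_jsonl(bad2)), "GAD-7")

  # missing column is a schema error naming the column
  csv2 <- tempfile(fileext = ".csv")
  write.csv(df[, c("text", "phq9")], csv2, row.names = FALSE)
  expect_error(read_corpus(csv2), "gad7")

  # empty file: empty corpus with a warning
  empty <- tempfile(fileext = ".jsonl")
  file.create(empty)
  expect_warning(got0 <- read_corpus(empty), "empty")
  expect_equal(nrow(got0), 0L)
})

test_that("corpus round-trips through write_corpus/read_corpus", {
  corpus <- tiny_corpus(n = 20L, seed = 2L)
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_equal(back$text, corpus$text)
  expect_equal(back$phq9, corpus$phq9)
  expect_equal(back$gad7, corpus$gad7)
})

test_that("clean_text strips markup but keeps emotive punctuation", {
  expect_equal(clean_text("开心！！！<br/>"),
               "开心！！！")
  expect_equal(clean_text("abc"), "abc")
  out <- clean_text("###")
  expect_equal(out[[1]], "")
  expect_equal(attr(out, "flagged"), 1L)
  # URLs and control characters removed, whitespace collapsed
  expect_equal(clean_text("see http://x.test/page  now"), "see now")
  # full-width comma normalized, question/exclamation marks preserved
  expect_equal(clean_text("你好，吗？"),
               "你好,吗？")
  expect_equal(clean_text("wait~ what?!"), "wait~ what?!")
})

test_that("tokenize truncates at max_len and marks real tokens", {
  tok <- build_tokenizer(c("a b c d e", "f g h"), mode = "whitespace")
  long_text <- paste(rep("a", 120), collapse = " ")
  s <- tokenize(long_text, tok, max_len = 96L)
  expect_equal(s$length, 96L)
  expect_equal(length(s$token_ids), 96L)
  expect_equal(s$attention_mask, rep(1L, 96L))

  s2 <- tokenize("a b c d", tok, max_len = 96L)
  expect_equal(s2$length, 5L)  # [CLS] + 4 tokens
  expect_equal(s2$token_ids[1], tok$cls_id)

  # unknown tokens map to the reserved UNK id, never fail
  s3 <- tokenize("zz qq", tok, max_len = 96L)
  expect_equal(s3$token_ids[-1], rep(tok$unk_id, 2L))

  expect_error(tokenize("", tok), "empty")
})

test_that("severity_bin uses the 0-4 / 5-9 / >=10 scheme and is monotone", {
  expect_equal(as.character(severity_bin(c(0L, 4L, 5L, 9L, 10L, 27L))),
               c("mild", "mild", "moderate", "moderate", "severe", "severe"))
  expect_error(severity_bin(-1L), "non-negative")
  # monotone non-decreasing in score
  bins <- as.integer(severity_bin(0:27))
  expect_true(all(diff(bins) >= 0))
})

test_that("screen_positive cuts at 10 on both scales", {
  expect_true(screen_positive(10L, "phq9"))
  expect_false(screen_positive(9L, "gad7"))
  expect_false(screen_positive(0L, "phq9"))
  expect_true(screen_positive(21L, "gad7"))
  expect_error(screen_positive(22L, "gad7"), "out of range")
})

test_that("stratified_split reproduces the 1,020/128/127 bookkeeping", {
  corpus <- tiny_corpus(n = 1275L, seed = 3L)
  sp <- stratified_split(corpus, seed = 1L)
  expect_equal(nrow(sp$train), 1020L)
  expect_equal(nrow(sp$validation), 128L)
  expect_equal(nrow(sp$test), 127L)
})

test_that("stratified_split conserves counts and is deterministic", {
  for (n in c(50L, 137L, 600L)) {
    corpus <- tiny_corpus(n = n, seed = n)
    sp <- stratified_split(corpus, seed = 9L)
    # disjoint and exhaustive
    ids <- c(sp$train$record_id, sp$validation$record_id, sp$test$record_id)
    expect_equal(sort(ids), sort(corpus$record_id))
    expect_equal(anyDuplicated(ids), 0L)
    # identical seed, identical membership
    sp2 <- stratified_split(corpus, seed = 9L)
    expect_identical(sp$train$record_id, sp2$train$record_id)
    # different seed: same stratum tallies, different membership
    sp3 <- stratified_split(corpus, seed = 10L)
    expect_equal(unclass(sp3$stratum_table), unclass(sp$stratum_table))
    expect_false(identical(sp$train$record_id, sp3$train$record_id))
  }
})

test_that("stratified_split keeps per-stratum proportions within one sample", {
  corpus <- tiny_corpus(n = 900L, seed = 17L)
  sp <- stratified_split(corpus, seed = 4L)
  tab <- sp$stratum_table
  totals <- colSums(tab)
  for (part in c("train", "validation", "test")) {
    share <- sum(tab[part, ]) / sum(totals)
    ideal <- totals * share
    expect_true(all(abs(tab[part, ] - ideal) <= 1 + 1e-9),
                info = part)
  }
})

test_that("single-stratum ten-record corpus splits exactly 8/1/1", {
  corpus <- data.frame(
    record_id = sprintf("r%02d", 1:10),
    text = rep("ok fine", 10), phq9 = rep(2L, 10), gad7 = rep(1L, 10),
    subject_id = NA_character_, cohort = NA_character_, synthetic = FALSE,
    stringsAsFactors = FALSE)
  sp <- stratified_split(corpus, seed = 5L)
  expect_equal(c(nrow(sp$train), nrow(sp$validation), nrow(sp$test)),
               c(8L, 1L, 1L))
})

test_that("tiny strata are routed to train with a warning", {
  corpus <- rbind(
    tiny_corpus(n = 40L, seed = 1L,
                imbalance = c(mild = 1, moderate = 0, severe = 0)),
    data.frame(record_id = c("x1", "x2"), text = c("sad cry", "cry sad"),
               phq9 = c(20L, 21L), gad7 = c(15L, 16L),
               subject_id = NA_character_, cohort = NA_character_,
               synthetic = TRUE, stringsAsFactors = FALSE))
  expect_warning(sp <- stratified_split(corpus, seed = 2L), "fewer than 3")
  expect_true(all(c("x1", "x2") %in% sp$train$record_id))
})

test_that("subject-grouped split keeps a subject's records together", {
  cfg <- generator_config(n_records = 40L, texts_per_subject = c(3L, 3L),
                          seed = 21L)
  corpus <- generate_corpus(cfg)
  sp <- stratified_split(corpus, seed = 2L, group_by_subject = TRUE)
  for (part in c("train", "validation", "test")) {
    subj <- unique(sp[[part]]$subject_id)
    other <- setdiff(c("train", "validation", "test"), part)
    for (o in other) {
      expect_equal(length(intersect(subj, unique(sp[[o]]$subject_id))), 0L)
    }
  }
})
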