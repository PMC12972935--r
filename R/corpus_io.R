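# Scale ranges for the two instruments.
.PHQ9_MAX <- 27L
.GAD7_MAX <- 21L

.SEVERITY_LEVELS <- c("mild", "moderate", "severe")

#' Read a labeled text corpus
#'
#' Reads a corpus of free-text responses labeled with PHQ-9 and GAD-7 total
#' scores from JSONL (one object per line, UTF-8) or CSV (header row).
#' Required fields are `text`, `phq9` and `gad7`; `record_id`, `subject_id`,
#' `cohort` and `synthetic` are optional and filled with defaults when absent.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"` or `"csv"`. Defaults to the file extension.
#' @return A data.frame with columns `record_id`, `text`, `phq9`, `gad7`,
#'   `subject_id`, `cohort`, `synthetic` — one row per record. Scores are
#'   validated against the scale ranges (PHQ-9 in 0–27, GAD-7 in 0–21).
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warning("empty corpus file: ", path)
      return(empty_corpus())
    }
    recs <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(
        record_id = as.character(r$record_id %||% NA_character_),
        text = as.character(r$text %||% NA_character_),
        phq9 = as.numeric(r$phq9 %||% NA_real_),
        gad7 = as.numeric(r$gad7 %||% NA_real_),
        subject_id = as.character(r$subject_id %||% NA_character_),
        cohort = as.character(r$cohort %||% NA_character_),
        synthetic = isTRUE(r$synthetic),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    if (nrow(df) == 0L) {
      warning("empty corpus file: ", path)
      return(empty_corpus())
    }
    for (col in c("record_id", "subject_id", "cohort")) {
      if (!col %in% names(df)) df[[col]] <- NA_character_
    }
    if (!"synthetic" %in% names(df)) df$synthetic <- FALSE
    df$synthetic <- as.logical(df$synthetic)
    df$synthetic[is.na(df$synthetic)] <- FALSE
  }
  validate_corpus(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_corpus <- function() {
  data.frame(
    record_id = character(), text = character(),
    phq9 = numeric(), gad7 = numeric(),
    subject_id = character(), cohort = character(), synthetic = logical(),
    stringsAsFactors = FALSE
  )
}

#' Validate a corpus data.frame
#'
#' Checks the schema (required columns) and the score ranges. Missing
#' `record_id`s are filled with row-index identifiers.
#'
#' @param df A corpus data.frame.
#' @return The validated (possibly completed) data.frame.
#' @export
validate_corpus <- function(df) {
  required <- c("text", "phq9", "gad7")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("corpus schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_corpus())
  if (!"record_id" %in% names(df) || all(is.na(df$record_id))) {
    df$record_id <- sprintf("r%05d", seq_len(nrow(df)))
  }
  if (!"subject_id" %in% names(df)) df$subject_id <- NA_character_
  if (!"cohort" %in% names(df)) df$cohort <- NA_character_
  if (!"synthetic" %in% names(df)) df$synthetic <- FALSE
  bad_phq <- which(is.na(df$phq9) | df$phq9 < 0 | df$phq9 > .PHQ9_MAX |
                     df$phq9 != round(df$phq9))
  if (length(bad_phq) > 0L) {
    stop("PHQ-9 score out of range [0, 27] for record(s): ",
         paste(utils::head(df$record_id[bad_phq], 5L), collapse = ", "))
  }
  bad_gad <- which(is.na(df$gad7) | df$gad7 < 0 | df$gad7 > .GAD7_MAX |
                     df$gad7 != round(df$gad7))
  if (length(bad_gad) > 0L) {
    stop("GAD-7 score out of range [0, 21] for record(s): ",
         paste(utils::head(df$record_id[bad_gad], 5L), collapse = ", "))
  }
  df$phq9 <- as.integer(df$phq9)
  df$gad7 <- as.integer(df$gad7)
  known_cohorts <- c("junior_high", "high_school", "university")
  bad_cohort <- !is.na(df$cohort) & !(df$cohort %in% known_cohorts)
  if (any(bad_cohort)) {
    stop("unknown cohort value(s): ",
         paste(unique(df$cohort[bad_cohort]), collapse = ", "))
  }
  rownames(df) <- NULL
  df[, c("record_id", "text", "phq9", "gad7", "subject_id", "cohort",
         "synthetic")]
}

#' Write a corpus as JSONL
#'
#' @param corpus A corpus data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- as.list(corpus[i, , drop = FALSE])
    rec <- lapply(rec, function(x) x[[1]])
    rec <- rec[!vapply(rec, function(x) is.na(x) || is.null(x), logical(1))]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

# Default whitelist of emotion-expressive punctuation kept by clean_text().
.EMOTIVE_PUNCT <- c("!", "！", "?", "？", "~", "…")

#' Clean raw text
#'
#' Removes control characters, URLs and markup, normalizes full-width
#' punctuation to one form, preserves emotion-expressive punctuation
#' (exclamation/question marks, ellipses, tildes), and collapses whitespace.
#'
#' @param raw A character vector of raw texts.
#' @param keep_punct Characters to preserve; defaults to the emotive set.
#' @return Cleaned character vector. Texts that become empty are returned as
#'   `""` with attribute `flagged` marking their positions.
#' @export
clean_text <- function(raw, keep_punct = .EMOTIVE_PUNCT) {
  x <- enc2utf8(as.character(raw))
  # strip markup tags and URLs before touching punctuation
  x <- gsub("<[^>]*>", " ", x, perl = TRUE)
  x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x, perl = TRUE)
  # control characters
  x <- gsub("[[:cntrl:]]", " ", x, perl = TRUE)
  # normalize common full-width punctuation to half-width, except the
  # emotion-expressive set which is kept verbatim
  full <- c("，", "。", "；", "：", "“", "”",
            "（", "）", "、")
  half <- c(",", ".", ";", ":", "\"", "\"", "(", ")", ",")
  for (i in seq_along(full)) x <- gsub(full[i], half[i], x, fixed = TRUE)
  # drop remaining special characters: keep letters, digits, CJK, whitespace,
  # basic sentence punctuation and the emotive whitelist
  keep <- paste0(vapply(keep_punct, function(p) paste0("\\Q", p, "\\E"),
                        character(1)), collapse = "")
  pattern <- paste0("[^[:alnum:][:space:]\\p{Han}.,;:\"()", keep, "]")
  x <- gsub(pattern, " ", x, perl = TRUE)
  x <- gsub("[[:space:]]+", " ", x, perl = TRUE)
  x <- trimws(x)
  flagged <- which(!nzchar(x))
  if (length(flagged) > 0L) attr(x, "flagged") <- flagged
  x
}

#' Build a vocabulary from a corpus
#'
#' Tokens are ranked by frequency; ids 1 and 2 are reserved for `[UNK]` and
#' `[CLS]`.
#'
#' @param texts Character vector of (cleaned) texts.
#' @param mode `"whitespace"` or `"char"` segmentation.
#' @param max_vocab Maximum vocabulary size including reserved ids.
#' @return A tokenizer handle (list with `vocab`, `mode`, `unk_id`, `cls_id`).
#' @export
build_tokenizer <- function(texts, mode = c("whitespace", "char"),
                            max_vocab = 5000L) {
  mode <- match.arg(mode)
  toks <- unlist(lapply(texts, segment_text, mode = mode))
  tab <- sort(table(toks), decreasing = TRUE)
  words <- names(tab)[seq_len(min(length(tab), max_vocab - 2L))]
  vocab <- stats::setNames(seq_along(words) + 2L, words)
  structure(list(vocab = vocab, mode = mode, unk_id = 1L, cls_id = 2L,
                 vocab_size = length(vocab) + 2L),
            class = "phqgad_tokenizer")
}

segment_text <- function(text, mode) {
  if (mode == "whitespace") {
    toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  } else {
    toks <- strsplit(gsub("[[:space:]]", "", text), "")[[1]]
  }
  toks[nzchar(toks)]
}

#' Tokenize a text into a fixed-length sample
#'
#' Maps a text through a tokenizer handle to integer token ids, prepending the
#' `[CLS]` id and truncating at `max_len` tokens. Unknown tokens map to the
#' reserved `[UNK]` id.
#'
#' @param text A single string.
#' @param tokenizer A handle from [build_tokenizer()].
#' @param max_len Maximum sequence length (default 96).
#' @return A list with `token_ids`, `attention_mask` (all ones — padding is a
#'   batching concern), and `length`.
#' @export
tokenize <- function(text, tokenizer, max_len = 96L) {
  stopifnot(inherits(tokenizer, "phqgad_tokenizer"), max_len >= 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    stop("cannot tokenize empty text; clean_text() flags these upstream")
  }
  toks <- segment_text(text, tokenizer$mode)
  ids <- unname(tokenizer$vocab[toks])
  ids[is.na(ids)] <- tokenizer$unk_id
  ids <- c(tokenizer$cls_id, ids)
  if (length(ids) > max_len) ids <- ids[seq_len(max_len)]
  list(token_ids = as.integer(ids),
       attention_mask = rep(1L, length(ids)),
       length = length(ids))
}

#' Bin a score into a severity level
#'
#' Three-level scheme used for both scales: mild 0–4, moderate 5–9,
#' severe 10 points and above.
#'
#' @param score Integer score vector.
#' @return Factor with levels `mild`, `moderate`, `severe`.
#' @export
severity_bin <- function(score) {
  if (any(is.na(score)) || any(score < 0)) {
    stop("severity_bin: scores must be non-negative")
  }
  cut(score, breaks = c(-Inf, 4.5, 9.5, Inf), labels = .SEVERITY_LEVELS,
      right = TRUE)
}

#' Binary clinical screen
#'
#' Positive screen at score >= 10 on either scale (the standard clinical
#' cutoff for both PHQ-9 and GAD-7).
#'
#' @param score Integer score vector.
#' @param scale `"phq9"` or `"gad7"` (same threshold; kept for range checks).
#' @return Logical vector.
#' @export
screen_positive <- function(score, scale = c("phq9", "gad7")) {
  scale <- match.arg(scale)
  max_ok <- if (scale == "phq9") .PHQ9_MAX else .GAD7_MAX
  if (any(score < 0 | score > max_ok)) {
    stop("score out of range for scale ", scale)
  }
  score >= 10
}

#' Stratified train/validation/test split
#'
#' Splits a corpus in the given ratios, stratified on the joint PHQ-9 x GAD-7
#' severity bins (3 x 3 grid). Global part sizes use the rounding convention
#' train = round(0.8 N), validation = ceiling of the remainder / 2, test =
#' rest, so N = 1,275 yields 1,020 / 128 / 127. Per-part allocation across
#' strata uses largest-remainder apportionment, keeping every stratum's
#' representation within one sample of proportionality.
#'
#' @param corpus Corpus data.frame.
#' @param ratios Positive length-3 numeric, default `c(8, 1, 1)`.
#' @param seed Integer seed; membership is deterministic given
#'   (corpus, ratios, seed).
#' @param group_by_subject If `TRUE`, all records of a subject go to the same
#'   part (stratum taken from the subject's first record).
#' @return A list with data.frames `train`, `validation`, `test`, plus `seed`
#'   and a `stratum_table` of per-stratum counts.
#' @export
stratified_split <- function(corpus, ratios = c(8, 1, 1), seed = 1L,
                             group_by_subject = FALSE) {
  stopifnot(nrow(corpus) > 0L, length(ratios) == 3L, all(ratios > 0))
  units <- corpus
  if (group_by_subject && !all(is.na(corpus$subject_id))) {
    first <- !duplicated(corpus$subject_id)
    units <- corpus[first, , drop = FALSE]
  }
  n <- nrow(units)
  frac <- ratios / sum(ratios)
  n_train <- round(frac[1] * n)
  rem <- n - n_train
  # validation receives the larger half of the remainder when odd
  n_val <- ceiling(rem * frac[2] / (frac[2] + frac[3]))
  n_test <- rem - n_val
  stratum <- interaction(severity_bin(units$phq9), severity_bin(units$gad7),
                         drop = FALSE)
  rng <- local_rng(seed)
  ord <- sample.int(n)  # shuffle once; allocation walks this order
  restore_rng(rng)
  targets <- c(train = n_train, validation = n_val, test = n_test)
  assign_part <- rep(NA_character_, n)
  remaining <- split(ord, stratum[ord], drop = TRUE)
  # tiny strata go wholly to train
  small <- names(remaining)[vapply(remaining, length, integer(1)) < 3L]
  for (s in small) {
    assign_part[remaining[[s]]] <- "train"
    warning("stratum ", s, " has fewer than 3 samples; allocated to train")
  }
  remaining <- remaining[setdiff(names(remaining), small)]
  pre_train <- sum(assign_part == "train", na.rm = TRUE)
  avail <- vapply(remaining, length, integer(1))
  taken <- stats::setNames(rep(0L, length(remaining)), names(remaining))
  for (part in c("train", "validation", "test")) {
    tgt <- targets[[part]] - if (part == "train") pre_train else 0L
    tgt <- max(tgt, 0L)
    left <- avail - taken
    if (part == "test") {
      quota <- left
    } else {
      ideal <- left * tgt / max(sum(left), 1L)
      quota <- floor(ideal)
      short <- tgt - sum(quota)
      if (short > 0L) {
        frac_rem <- ideal - quota
        # deterministic tie-break: larger remainder first, then stratum name
        extra_order <- order(-frac_rem, names(left))
        can_take <- extra_order[quota[extra_order] < left[extra_order]]
        bump <- utils::head(can_take, short)
        quota[bump] <- quota[bump] + 1L
      }
    }
    for (s in names(remaining)) {
      q <- quota[[s]]
      if (q <= 0L) next
      idx <- remaining[[s]][(taken[[s]] + 1L):(taken[[s]] + q)]
      assign_part[idx] <- part
      taken[[s]] <- taken[[s]] + q
    }
  }
  if (group_by_subject && !all(is.na(corpus$subject_id))) {
    part_by_subject <- stats::setNames(assign_part, units$subject_id)
    assign_full <- part_by_subject[corpus$subject_id]
  } else {
    assign_full <- assign_part
  }
  out <- list(
    train = corpus[assign_full == "train", , drop = FALSE],
    validation = corpus[assign_full == "validation", , drop = FALSE],
    test = corpus[assign_full == "test", , drop = FALSE],
    seed = seed
  )
  rownames(out$train) <- rownames(out$validation) <- rownames(out$test) <- NULL
  # report counts at the allocation-unit level (records, or subjects when
  # grouping): stratum was computed on units
  out$stratum_table <- table(
    part = factor(assign_part, c("train", "validation", "test")),
    stratum = stratum
  )
  class(out) <- "phqgad_split"
  out
}

#' Write split manifests
#'
#' Writes each part as JSONL plus a per-stratum count report as CSV.
#'
#' @param split A `phqgad_split` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "validation", "test")) {
    write_corpus(split[[part]], file.path(dir, paste0(part, ".jsonl")))
  }
  rep <- as.data.frame(split$stratum_table)
  utils::write.csv(rep, file.path(dir, "split_report.csv"), row.names = FALSE)
  invisible(dir)
}

# Seed scoping: run code under a given seed, then restore the caller's RNG
# state so library code never clobbers the session stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  expr
}
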