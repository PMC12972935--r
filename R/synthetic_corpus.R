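#' Default symbolic lexicon for synthetic corpora
#'
#' Three token categories with per-severity emission rates: emotional tokens
#' track the depression (PHQ-9) severity bin, somatic tokens track the anxiety
#' (GAD-7) bin, neutral tokens fill the rest. Rates are probabilities per
#' token position, rows ordered mild/moderate/severe.
#'
#' @param strength `"default"` for a moderate signal or `"strong"` for a
#'   corpus a bag-of-words linear classifier separates almost perfectly —
#'   used to test that downstream models can recover a signal that is there.
#' @return A lexicon list (`emotional`, `somatic`, `neutral` token vectors and
#'   an `rates` 3x2 matrix of per-severity emission probabilities for the
#'   emotional and somatic categories).
#' @export
default_lexicon <- function(strength = c("default", "strong")) {
  strength <- match.arg(strength)
  rates <- switch(strength,
    default = cbind(emotional = c(0.08, 0.20, 0.35),
                    somatic   = c(0.06, 0.18, 0.32)),
    strong  = cbind(emotional = c(0.02, 0.25, 0.60),
                    somatic   = c(0.02, 0.22, 0.55))
  )
  rownames(rates) <- .SEVERITY_LEVELS
  list(
    emotional = c("sad", "hopeless", "cry", "worthless", "lonely", "numb",
                  "guilty", "empty", "despair"),
    somatic   = c("headache", "insomnia", "fatigue", "stomachache", "dizzy",
                  "palpitations", "tense", "restless", "sweating"),
    neutral   = c("school", "homework", "friend", "today", "weather", "class",
                  "lunch", "game", "music", "weekend", "teacher", "bus"),
    rates = rates
  )
}

#' Generator configuration for synthetic labeled corpora
#'
#' The generator emulates the structure the screening model assumes: PHQ-9 and
#' GAD-7 scores correlated through a Gaussian copula, a severity-imbalanced
#' population with the severe stratum rarest, and vocabulary whose emission
#' rates increase with severity (emotional tokens with depression, somatic
#' tokens with anxiety).
#'
#' @param n_records Number of records (default 1275, the reference cohort
#'   size).
#' @param score_correlation Target latent correlation between the two scores
#'   (default 0.7 — comorbid scales are strongly correlated).
#' @param imbalance Named severity proportions (must sum to 1); default makes
#'   severe the rarest stratum.
#' @param lexicon A lexicon list, see [default_lexicon()].
#' @param text_length_range Integer pair: min/max tokens per text.
#' @param texts_per_subject Integer pair: records per subject; `c(1, 1)`
#'   keeps one record per subject so counts match cohort-level bookkeeping.
#' @param seed Integer seed.
#' @return A `phqgad_gen_config` list.
#' @export
generator_config <- function(n_records = 1275L,
                             score_correlation = 0.7,
                             imbalance = c(mild = 0.45, moderate = 0.35,
                                           severe = 0.20),
                             lexicon = default_lexicon(),
                             text_length_range = c(8L, 20L),
                             texts_per_subject = c(1L, 1L),
                             seed = 1L) {
  stopifnot(n_records >= 1L,
            score_correlation >= -1, score_correlation <= 1,
            abs(sum(imbalance) - 1) < 1e-9,
            all(imbalance >= 0),
            all(.SEVERITY_LEVELS %in% names(imbalance)),
            all(lexicon$rates >= 0),
            length(text_length_range) == 2L,
            text_length_range[1] >= 1L,
            text_length_range[2] >= text_length_range[1])
  structure(list(n_records = as.integer(n_records),
                 score_correlation = score_correlation,
                 imbalance = imbalance[.SEVERITY_LEVELS],
                 lexicon = lexicon,
                 text_length_range = as.integer(text_length_range),
                 texts_per_subject = as.integer(texts_per_subject),
                 seed = as.integer(seed)),
            class = "phqgad_gen_config")
}

# Severity bin score supports for each scale.
.BIN_RANGES <- list(
  phq9 = list(mild = 0:4, moderate = 5:9, severe = 10:27),
  gad7 = list(mild = 0:4, moderate = 5:9, severe = 10:21)
)

# Map a uniform draw through the severity-targeted quantile table of one
# scale: the unit interval is carved into severity segments by the imbalance
# proportions, and each segment maps uniformly onto the integer scores of its
# bin. Comonotone inputs therefore yield comonotone scores.
quantile_score <- function(u, scale, imbalance) {
  cum <- cumsum(imbalance)
  bins <- .BIN_RANGES[[scale]]
  sev_idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE,
                          all.inside = TRUE)
  lo <- c(0, cum)[sev_idx]
  hi <- cum[sev_idx]
  # rescale u within its severity segment, then index into the bin's scores
  v <- (u - lo) / pmax(hi - lo, 1e-12)
  vapply(seq_along(u), function(i) {
    scores <- bins[[sev_idx[i]]]
    scores[pmin(length(scores), 1L + floor(v[i] * length(scores)))]
  }, integer(1))
}

#' Sample one or more correlated PHQ-9/GAD-7 score pairs
#'
#' Draws a latent bivariate normal with the configured correlation and maps
#' each marginal through a severity-targeted quantile table to integer scores
#' (Gaussian copula), so marginal severity proportions match the imbalance
#' targets while the rank correlation tracks `score_correlation`.
#'
#' @param config A [generator_config()].
#' @param n Number of pairs.
#' @return An `n` x 2 integer matrix with columns `phq9`, `gad7`.
#' @export
sample_score_pair <- function(config, n = 1L) {
  rho <- config$score_correlation
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  u1 <- stats::pnorm(z1)
  u2 <- stats::pnorm(z2)
  cbind(phq9 = quantile_score(u1, "phq9", config$imbalance),
        gad7 = quantile_score(u2, "gad7", config$imbalance))
}

#' Render a symbolic text for a score pair
#'
#' Token categories are drawn with emission rates monotone in severity:
#' emotional tokens at the rate of the PHQ-9 severity bin, somatic tokens at
#' the rate of the GAD-7 bin, neutral tokens otherwise. Within a category,
#' tokens are uniform. Text length is uniform on `text_length_range`.
#'
#' @param phq,gad Integer scores.
#' @param config A [generator_config()].
#' @return A single space-joined token string.
#' @export
render_text <- function(phq, gad, config) {
  lex <- config$lexicon
  p_emo <- lex$rates[as.character(severity_bin(phq)), "emotional"]
  p_som <- lex$rates[as.character(severity_bin(gad)), "somatic"]
  p_neu <- max(0, 1 - p_emo - p_som)
  lo <- config$text_length_range[1]; hi <- config$text_length_range[2]
  len <- lo + sample.int(hi - lo + 1L, 1L) - 1L  # safe when lo == hi
  cat_draw <- sample(c("emotional", "somatic", "neutral"), len, replace = TRUE,
                     prob = c(p_emo, p_som, p_neu))
  toks <- vapply(cat_draw, function(cat) sample(lex[[cat]], 1L), character(1))
  paste(toks, collapse = " ")
}

#' Generate a labeled synthetic corpus
#'
#' @param config A [generator_config()].
#' @return A corpus data.frame (`synthetic = TRUE` on every record) with the
#'   configured size, score correlation and severity imbalance.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "phqgad_gen_config"))
  with_seed(config$seed, {
    tps <- config$texts_per_subject
    n_subj <- config$n_records
    reps <- if (tps[2] > tps[1]) {
      sample(tps[1]:tps[2], n_subj, replace = TRUE)
    } else rep(tps[1], n_subj)
    scores <- sample_score_pair(config, n_subj)
    rows <- vector("list", sum(reps))
    k <- 0L
    for (s in seq_len(n_subj)) {
      for (r in seq_len(reps[s])) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          record_id = sprintf("s%04d_t%02d", s, r),
          text = render_text(scores[s, "phq9"], scores[s, "gad7"], config),
          phq9 = scores[s, "phq9"],
          gad7 = scores[s, "gad7"],
          subject_id = sprintf("s%04d", s),
          cohort = sample(c("junior_high", "high_school", "university"), 1L),
          synthetic = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df
  })
}
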