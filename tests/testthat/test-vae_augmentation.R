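# Conditional VAE: posterior contract, reparameterization, KL closed form,
# decoding, quality filters, class balance, and the augmentation pipeline.

small_vae_config <- function(seed = 1L, latent = 8L) {
  vae_config(latent_dim = latent, emb_dim = 6L, enc_hidden = 8L,
             dec_hidden = 12L, cond_dim = 4L, pos_dim = 4L,
             vocab_size = 30L, max_len = 24L, seed = seed)
}

test_that("posterior heads emit the configured latent dimension", {
  cfg <- vae_config(vocab_size = 30L)  # default latent 128
  vae <- phqgad:::init_vae(cfg, seed = 1L)
  code <- encode_posterior(c(3L, 7L, 12L), vae)
  expect_equal(length(code$mu), 128L)
  expect_equal(length(code$log_var), 128L)
  # determinism and finite variances
  code2 <- encode_posterior(c(3L, 7L, 12L), vae)
  expect_identical(code, code2)
  expect_true(all(is.finite(exp(code$log_var))))
  expect_true(all(exp(code$log_var) > 0))
})

test_that("reparameterization is mu + sigma * eps", {
  code <- list(mu = c(2, -1), log_var = c(-Inf, -Inf))
  code$log_var <- c(-60, -60)  # sigma ~ 0
  withr::with_seed(1L, z <- reparameterize(code))
  expect_equal(z, code$mu, tolerance = 1e-10)
  code2 <- list(mu = c(0.5, -0.5), log_var = c(0, 0))
  withr::with_seed(2L, {
    zs <- replicate(10000, reparameterize(code2))
    expect_lt(max(abs(rowMeans(zs) - code2$mu)), 4 / 100)
  })
  withr::with_seed(3L, za <- reparameterize(code2))
  withr::with_seed(3L, zb <- reparameterize(code2))
  expect_identical(za, zb)
})

test_that("Gaussian KL matches its closed form and a numerical oracle", {
  expect_equal(gaussian_kl(rep(0, 4), rep(0, 4)), 0)
  expect_equal(gaussian_kl(c(1, 0, 0), c(0, 0, 0)), 0.5)
  withr::with_seed(4L, {
    mu <- rnorm(6); lv <- rnorm(6, sd = 0.5)
  })
  oracle <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv)
  expect_lt(abs(gaussian_kl(mu, lv) - oracle), 1e-9)
  # 1-D numerical-integration oracle: KL = E_q[log q - log p]
  m <- 0.7; s2 <- 1.6
  f <- function(x) {
    q <- dnorm(x, m, sqrt(s2))
    q * (dnorm(x, m, sqrt(s2), log = TRUE) - dnorm(x, log = TRUE))
  }
  num <- integrate(f, -12, 12, rel.tol = 1e-10)$value
  expect_lt(abs(gaussian_kl(m, log(s2)) - num), 1e-4)
})

test_that("vae_training_loss composes reconstruction and weighted KL", {
  logits <- matrix(0, 2, 5)  # uniform predictions
  code <- list(mu = rep(0, 3), log_var = rep(0, 3))
  l <- vae_training_loss(logits, c(1L, 4L), code, kl_weight = 1)
  expect_equal(l$kl, 0)
  expect_equal(l$recon, log(5), tolerance = 1e-9)
  code2 <- list(mu = c(1, 0, 0), log_var = rep(0, 3))
  l2 <- vae_training_loss(logits, c(1L, 4L), code2, kl_weight = 0.5)
  expect_equal(l2$total, log(5) + 0.5 * 0.5, tolerance = 1e-9)
})

test_that("decoding is conditioned, tempered and deterministic", {
  cfg <- small_vae_config()
  vae <- phqgad:::init_vae(cfg, seed = 2L)
  z <- rnorm(cfg$latent_dim)
  # temperature -> 0 reduces to greedy decoding
  greedy <- vae_decode(z, c(1L, 1L), vae, len = 6L, temperature = 1e-9)
  argmax <- vae_decode(z, c(1L, 1L), vae, len = 6L, sample = FALSE)
  expect_equal(greedy$ids, argmax$ids)
  # same (z, y, seed) -> same text
  withr::with_seed(5L, a <- vae_decode(z, c(2L, 3L), vae, len = 6L))
  withr::with_seed(5L, b <- vae_decode(z, c(2L, 3L), vae, len = 6L))
  expect_identical(a$ids, b$ids)
  # probs rows are simplexes
  expect_lt(max(abs(rowSums(a$probs) - 1)), 1e-9)
})

test_that("trained decoder shifts vocabulary with the severity condition", {
  corpus <- tiny_corpus(n = 250L, seed = 41L, strength = "strong")
  tok <- build_tokenizer(corpus$text)
  cfg <- vae_config(latent_dim = 16L, vocab_size = tok$vocab_size,
                    seed = 41L)
  vae <- train_vae(corpus, tok, cfg, epochs = 8L)
  lex <- default_lexicon("strong")
  distress <- c(lex$emotional, lex$somatic)
  vocab_rev <- c("[UNK]", "[CLS]", names(tok$vocab))
  count_distress <- function(y, n = 250L) {
    withr::with_seed(42L, {
      mean(vapply(seq_len(n), function(i) {
        z <- rnorm(cfg$latent_dim)  # prior draw
        ids <- vae_decode(z, y, vae, len = 12L)$ids
        sum(vocab_rev[ids] %in% distress)
      }, numeric(1)))
    })
  }
  expect_gt(count_distress(c(3L, 3L)), count_distress(c(1L, 1L)))
})

test_that("quality filters implement the four mechanisms", {
  cfg <- small_vae_config()
  clf <- function(text) list(phq_bin = 3L, gad_bin = 3L)
  flu <- function(text) 1
  # identical candidate: similarity passes, diversity fails
  r <- filter_generated("sad cry headache", "sad cry headache", c(3L, 3L),
                        cfg, consistency_clf = clf, fluency_fn = flu)
  expect_true(r$similarity)
  expect_false(r$diversity)
  expect_false(r$accept)
  # similarity exactly at the threshold fails (strictly above)
  r2 <- filter_generated("a", "b", c(3L, 3L), cfg,
                         similarity_fn = function(a, b) 0.7,
                         consistency_clf = clf, fluency_fn = flu)
  expect_false(r2$similarity)
  r3 <- filter_generated("a", "b", c(3L, 3L), cfg,
                         similarity_fn = function(a, b) 0.7 + 1e-9,
                         consistency_clf = clf, fluency_fn = flu)
  expect_true(r3$similarity)
  # consistency mismatch fails
  r4 <- filter_generated("sad cry", "sad weep", c(1L, 1L), cfg,
                         consistency_clf = clf, fluency_fn = flu)
  expect_false(r4$consistency)
  # empty candidate fails fluency
  r5 <- filter_generated("sad cry", "", c(3L, 3L), cfg,
                         consistency_clf = clf,
                         fluency_fn = function(text) 0)
  expect_false(r5$fluency)
  # missing pluggable model reports skipped (NA) and is excluded
  r6 <- filter_generated("sad cry", "weep sad", c(3L, 3L), cfg,
                         consistency_clf = NULL, fluency_fn = NULL)
  expect_true(is.na(r6$consistency))
  expect_true(is.na(r6$fluency))
})

test_that("class balance is the normalized stratum entropy", {
  mk <- function(phq, gad) {
    data.frame(record_id = sprintf("r%d", seq_along(phq)),
               text = "t", phq9 = phq, gad7 = gad,
               subject_id = NA_character_, cohort = NA_character_,
               synthetic = FALSE, stringsAsFactors = FALSE)
  }
  # uniform over three occupied strata -> 1
  u <- mk(c(2L, 7L, 12L), c(2L, 2L, 2L))
  expect_equal(class_balance(u), 1)
  # single stratum -> 0
  expect_equal(class_balance(mk(c(1L, 2L), c(1L, 2L))), 0)
  # proportions (0.5, 0.25, 0.25): H / log 3 = 1.5 ln 2 / ln 3
  p <- mk(c(2L, 2L, 7L, 12L), rep(2L, 4)) # strata mild, mild, mod, sev
  expect_equal(class_balance(p), (1.5 * log(2)) / log(3), tolerance = 1e-9)
})

test_that("pass-through augmentation doubles the corpus and keeps originals", {
  corpus <- tiny_corpus(n = 80L, seed = 51L)
  cfg <- vae_config(latent_dim = 8L, enc_hidden = 8L, dec_hidden = 12L,
                    seed = 51L)
  aug <- augment_to_balance(corpus, target_multiplier = 2.0, config = cfg,
                            filters = "none", vae_epochs = 2L)
  expect_equal(nrow(aug$corpus), 160L)
  expect_equal(aug$report$n_original, 80L)
  # superset property: originals appear unmodified
  orig <- aug$corpus[seq_len(80L), ]
  expect_identical(orig$text, corpus$text)
  expect_identical(orig$record_id, corpus$record_id)
  # generated records are flagged synthetic
  expect_true(all(aug$corpus$synthetic[81:160]))
  # multiplier 1.0 leaves the corpus unchanged
  aug1 <- augment_to_balance(corpus, target_multiplier = 1.0, config = cfg)
  expect_identical(aug1$corpus, corpus)
})

test_that("balance-targeted augmentation raises normalized entropy", {
  corpus <- tiny_corpus(n = 150L, seed = 52L,
                        imbalance = c(mild = 0.7, moderate = 0.2,
                                      severe = 0.1))
  cfg <- vae_config(latent_dim = 8L, enc_hidden = 8L, dec_hidden = 12L,
                    seed = 52L)
  aug <- augment_to_balance(corpus, target_multiplier = 1.5, config = cfg,
                            filters = "none", vae_epochs = 2L)
  expect_gt(aug$report$class_balance_after,
            aug$report$class_balance_before)
})

test_that("filters only remove candidates, never mutate accepted ones", {
  corpus <- tiny_corpus(n = 100L, seed = 53L)
  cfg <- vae_config(latent_dim = 16L, seed = 53L)
  aug <- suppressWarnings(
    augment_to_balance(corpus, target_multiplier = 1.2, config = cfg,
                       filters = "all", vae_epochs = 6L, budget_factor = 5))
  rep <- aug$report
  expect_lte(rep$n_accepted, rep$n_generated)
  expect_true(all(rep$n_passed <= rep$n_generated))
  # accepted candidates all clear the strict similarity threshold
  gen <- aug$corpus[aug$corpus$synthetic &
                      grepl("_aug", aug$corpus$record_id), ]
  if (nrow(gen) > 0L) {
    src_ids <- sub("_aug\\d+$", "", gen$record_id)
    for (i in seq_len(nrow(gen))) {
      src <- corpus[corpus$record_id == src_ids[i], ]
      expect_gt(cosine_similarity(src$text, gen$text[i]), 0.7)
    }
  }
})
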