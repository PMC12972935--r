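# Conditional text VAE for minority-class oversampling. The encoder is a
# bidirectional tanh recurrent network whose pooled states feed two affine
# heads producing the posterior mean and log-variance; the decoder emits a
# categorical token distribution at each position from the latent code, the
# severity-condition embeddings and a position embedding. Training maximizes
# the ELBO (token cross-entropy reconstruction + KL to the standard normal
# prior) with linear KL annealing to avoid posterior collapse.

.LOGVAR_CLAMP <- 8

#' VAE configuration
#'
#' @param latent_dim Latent dimension (default 128).
#' @param emb_dim Token embedding width of the VAE.
#' @param enc_hidden Recurrent hidden size per direction.
#' @param dec_hidden Decoder hidden width.
#' @param cond_dim Width of each severity-condition embedding.
#' @param pos_dim Width of the decoder position embedding.
#' @param vocab_size,max_len Must match the tokenizer in use.
#' @param temperature Sampling temperature for generation (> 0).
#' @param similarity_threshold Semantic-similarity acceptance threshold;
#'   candidates must score strictly above it (default 0.7).
#' @param min_diversity Minimum normalized edit distance from the source and
#'   from previously accepted candidates.
#' @param fluency_floor Minimum fluency score.
#' @param seed Integer seed.
#' @return A `phqgad_vae_config` list.
#' @export
vae_config <- function(latent_dim = 128L, emb_dim = 16L, enc_hidden = 32L,
                       dec_hidden = 64L, cond_dim = 8L, pos_dim = 8L,
                       vocab_size = 200L, max_len = 96L, temperature = 0.5,
                       similarity_threshold = 0.7, min_diversity = 0.1,
                       fluency_floor = 0.5, seed = 1L) {
  stopifnot(latent_dim >= 1L, temperature > 0,
            similarity_threshold > 0, similarity_threshold <= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 emb_dim = as.integer(emb_dim),
                 enc_hidden = as.integer(enc_hidden),
                 dec_hidden = as.integer(dec_hidden),
                 cond_dim = as.integer(cond_dim),
                 pos_dim = as.integer(pos_dim),
                 vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 temperature = temperature,
                 similarity_threshold = similarity_threshold,
                 min_diversity = min_diversity,
                 fluency_floor = fluency_floor,
                 seed = as.integer(seed)),
            class = "phqgad_vae_config")
}

init_vae <- function(config, seed = config$seed) {
  with_seed(seed, {
    de <- config$emb_dim; dh <- config$enc_hidden; dz <- config$latent_dim
    dc <- config$cond_dim; dp <- config$pos_dim; dd <- config$dec_hidden
    V <- config$vocab_size
    du <- dz + 2L * dc + dp
    p <- list(
      vemb = matrix(stats::rnorm(V * de, sd = 0.05), V, de),
      enc_f_Wx = glorot(de, dh), enc_f_Wh = glorot(dh, dh),
      enc_f_b = rep(0, dh),
      enc_b_Wx = glorot(de, dh), enc_b_Wh = glorot(dh, dh),
      enc_b_b = rep(0, dh),
      W_mu = glorot(2L * dh, dz), b_mu = rep(0, dz),
      W_lv = glorot(2L * dh, dz), b_lv = rep(0, dz),
      cemb_phq = matrix(stats::rnorm(3L * dc, sd = 0.05), 3L, dc),
      cemb_gad = matrix(stats::rnorm(3L * dc, sd = 0.05), 3L, dc),
      pemb = matrix(stats::rnorm(config$max_len * dp, sd = 0.05),
                    config$max_len, dp),
      dec_W1 = glorot(du, dd), dec_b1 = rep(0, dd),
      dec_W2 = glorot(dd, V), dec_b2 = rep(0, V)
    )
    structure(list(config = config, params = p), class = "phqgad_vae")
  })
}

# One recurrent direction; returns hidden-state matrix (len x dh).
rnn_dir <- function(X, Wx, Wh, b) {
  len <- nrow(X); dh <- ncol(Wx)
  H <- matrix(0, len, dh)
  h <- rep(0, dh)
  pre <- X %*% Wx
  for (t in seq_len(len)) {
    h <- tanh(pre[t, ] + drop(h %*% Wh) + b)
    H[t, ] <- h
  }
  H
}

#' Encode the approximate posterior of a sample
#'
#' Bidirectional recurrent encoding followed by two affine heads giving the
#' posterior mean and log-variance (clamped for numerical stability).
#'
#' @param ids Integer token-id vector (no reserved [CLS] needed).
#' @param vae A `phqgad_vae`.
#' @return List with `mu`, `log_var` (length `latent_dim`).
#' @export
encode_posterior <- function(ids, vae) {
  p <- vae$params
  X <- p$vemb[ids, , drop = FALSE]
  Hf <- rnn_dir(X, p$enc_f_Wx, p$enc_f_Wh, p$enc_f_b)
  Hb <- rnn_dir(X[rev(seq_len(nrow(X))), , drop = FALSE],
                p$enc_b_Wx, p$enc_b_Wh, p$enc_b_b)
  enc <- c(colMeans(Hf), colMeans(Hb))
  mu <- drop(enc %*% p$W_mu) + p$b_mu
  lv <- drop(enc %*% p$W_lv) + p$b_lv
  lv <- pmin(pmax(lv, -.LOGVAR_CLAMP), .LOGVAR_CLAMP)
  list(mu = mu, log_var = lv)
}

#' Reparameterized posterior sample
#'
#' `z = mu + sigma * eps`, `eps ~ N(0, I)`.
#'
#' @param code List with `mu` and `log_var`.
#' @return Latent vector `z`.
#' @export
reparameterize <- function(code) {
  eps <- stats::rnorm(length(code$mu))
  code$mu + exp(0.5 * code$log_var) * eps
}

#' Closed-form Gaussian KL to the standard normal prior
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) =
#'   0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param mu,log_var Posterior mean and log-variance vectors.
#' @return Non-negative scalar.
#' @export
gaussian_kl <- function(mu, log_var) {
  0.5 * sum(mu^2 + exp(log_var) - 1 - log_var)
}

# Decoder input matrix for a (z, condition) pair over `len` positions.
decoder_inputs <- function(z, y, vae, len) {
  p <- vae$params
  c_phq <- p$cemb_phq[y[1L], ]
  c_gad <- p$cemb_gad[y[2L], ]
  cond <- c(c_phq, c_gad)
  U <- cbind(matrix(z, len, length(z), byrow = TRUE),
             matrix(cond, len, length(cond), byrow = TRUE),
             p$pemb[seq_len(len), , drop = FALSE])
  U
}

#' Decode token distributions from a latent code and condition
#'
#' The severity condition (PHQ-9 bin, GAD-7 bin) is embedded and
#' concatenated to `z` at every decoding position, together with a position
#' embedding; a two-layer network emits one categorical token distribution
#' per position. Sampling applies temperature scaling to the logits;
#' `temperature -> 0` reduces to greedy (argmax) decoding.
#'
#' @param z Latent vector.
#' @param y Severity condition: integer pair (PHQ-9 bin, GAD-7 bin), 1-3.
#' @param vae A `phqgad_vae`.
#' @param len Number of positions to emit.
#' @param temperature Sampling temperature; default from config.
#' @param sample If `FALSE`, return greedy ids.
#' @return List with `probs` (len x vocab matrix of tempered distributions)
#'   and `ids` (sampled or greedy token ids).
#' @export
vae_decode <- function(z, y, vae, len, temperature = NULL, sample = TRUE) {
  p <- vae$params
  temperature <- temperature %||% vae$config$temperature
  U <- decoder_inputs(z, y, vae, len)
  Hd <- pmax(sweep(U %*% p$dec_W1, 2L, p$dec_b1, `+`), 0)
  logits <- sweep(Hd %*% p$dec_W2, 2L, p$dec_b2, `+`)
  if (temperature < 1e-6 || !sample) {
    ids <- max.col(logits, ties.method = "first")
    probs <- softmax(logits)
  } else {
    probs <- softmax(logits / temperature)
    ids <- vapply(seq_len(len), function(t) {
      sample.int(ncol(probs), 1L, prob = probs[t, ])
    }, integer(1))
  }
  list(probs = probs, ids = ids)
}

#' VAE training loss (negative ELBO) for one sample
#'
#' Token-level reconstruction cross-entropy plus `kl_weight` times the
#' closed-form Gaussian KL to the prior.
#'
#' @param logits len x vocab decoder logits.
#' @param target_ids True token ids.
#' @param code Posterior list (`mu`, `log_var`).
#' @param kl_weight KL annealing weight in `[0, 1]`.
#' @return List with `total`, `recon`, `kl`.
#' @export
vae_training_loss <- function(logits, target_ids, code, kl_weight = 1) {
  P <- softmax(logits)
  picked <- pmax(P[cbind(seq_along(target_ids), target_ids)], 1e-12)
  recon <- -mean(log(picked))
  kl <- gaussian_kl(code$mu, code$log_var)
  list(total = recon + kl_weight * kl, recon = recon, kl = kl)
}

# Full forward + backward for one sample; returns loss and parameter grads.
vae_sample_grad <- function(vae, ids, y, kl_weight) {
  p <- vae$params
  cfg <- vae$config
  len <- length(ids)
  X <- p$vemb[ids, , drop = FALSE]
  rev_idx <- rev(seq_len(len))
  Hf <- rnn_dir(X, p$enc_f_Wx, p$enc_f_Wh, p$enc_f_b)
  Hb <- rnn_dir(X[rev_idx, , drop = FALSE], p$enc_b_Wx, p$enc_b_Wh,
                p$enc_b_b)
  enc <- c(colMeans(Hf), colMeans(Hb))
  mu <- drop(enc %*% p$W_mu) + p$b_mu
  lv_raw <- drop(enc %*% p$W_lv) + p$b_lv
  lv <- pmin(pmax(lv_raw, -.LOGVAR_CLAMP), .LOGVAR_CLAMP)
  eps <- stats::rnorm(length(mu))
  z <- mu + exp(0.5 * lv) * eps
  U <- decoder_inputs(z, y, vae, len)
  Z1 <- sweep(U %*% p$dec_W1, 2L, p$dec_b1, `+`)
  Hd <- pmax(Z1, 0)
  logits <- sweep(Hd %*% p$dec_W2, 2L, p$dec_b2, `+`)
  loss <- vae_training_loss(logits, ids, list(mu = mu, log_var = lv),
                            kl_weight)
  # --- backward ---
  P <- softmax(logits)
  dlogits <- P
  dlogits[cbind(seq_len(len), ids)] <- dlogits[cbind(seq_len(len), ids)] - 1
  dlogits <- dlogits / len
  g <- list()
  g$dec_W2 <- crossprod(Hd, dlogits)
  g$dec_b2 <- colSums(dlogits)
  dHd <- dlogits %*% t(p$dec_W2)
  dZ1 <- dHd * (Z1 > 0)
  g$dec_W1 <- crossprod(U, dZ1)
  g$dec_b1 <- colSums(dZ1)
  dU <- dZ1 %*% t(p$dec_W1)
  dz_dim <- cfg$latent_dim; dc <- cfg$cond_dim
  dz <- colSums(dU[, seq_len(dz_dim), drop = FALSE])
  dcond_phq <- colSums(dU[, dz_dim + seq_len(dc), drop = FALSE])
  dcond_gad <- colSums(dU[, dz_dim + dc + seq_len(dc), drop = FALSE])
  dpemb_rows <- dU[, dz_dim + 2L * dc + seq_len(cfg$pos_dim), drop = FALSE]
  g$cemb_phq <- matrix(0, 3L, dc); g$cemb_phq[y[1L], ] <- dcond_phq
  g$cemb_gad <- matrix(0, 3L, dc); g$cemb_gad[y[2L], ] <- dcond_gad
  g$pemb <- matrix(0, cfg$max_len, cfg$pos_dim)
  g$pemb[seq_len(len), ] <- dpemb_rows
  # z = mu + exp(lv/2) * eps; KL grads; clamp zeroes grads outside range
  dmu <- dz + kl_weight * mu
  dlv <- dz * eps * 0.5 * exp(0.5 * lv) + kl_weight * 0.5 * (exp(lv) - 1)
  dlv[lv_raw < -.LOGVAR_CLAMP | lv_raw > .LOGVAR_CLAMP] <- 0
  g$W_mu <- outer(enc, dmu)
  g$b_mu <- dmu
  g$W_lv <- outer(enc, dlv)
  g$b_lv <- dlv
  denc <- drop(p$W_mu %*% dmu) + drop(p$W_lv %*% dlv)
  dh_pool_f <- denc[seq_len(cfg$enc_hidden)] / len
  dh_pool_b <- denc[cfg$enc_hidden + seq_len(cfg$enc_hidden)] / len
  dX <- matrix(0, len, cfg$emb_dim)
  bptt <- function(H, Xd, Wx, Wh, b, dh_pool) {
    dWx <- matrix(0, nrow(Wx), ncol(Wx))
    dWh <- matrix(0, nrow(Wh), ncol(Wh))
    db <- rep(0, length(b))
    dXl <- matrix(0, nrow(Xd), ncol(Xd))
    dh_next <- rep(0, ncol(Wh))
    for (t in rev(seq_len(nrow(Xd)))) {
      dh <- dh_pool + dh_next
      dpre <- dh * (1 - H[t, ]^2)
      hprev <- if (t > 1L) H[t - 1L, ] else rep(0, ncol(Wh))
      dWx <- dWx + outer(Xd[t, ], dpre)
      dWh <- dWh + outer(hprev, dpre)
      db <- db + dpre
      dXl[t, ] <- drop(Wx %*% dpre)
      dh_next <- drop(Wh %*% dpre)
    }
    list(dWx = dWx, dWh = dWh, db = db, dX = dXl)
  }
  bf <- bptt(Hf, X, p$enc_f_Wx, p$enc_f_Wh, p$enc_f_b, dh_pool_f)
  bb <- bptt(Hb, X[rev_idx, , drop = FALSE], p$enc_b_Wx, p$enc_b_Wh,
             p$enc_b_b, dh_pool_b)
  g$enc_f_Wx <- bf$dWx; g$enc_f_Wh <- bf$dWh; g$enc_f_b <- bf$db
  g$enc_b_Wx <- bb$dWx; g$enc_b_Wh <- bb$dWh; g$enc_b_b <- bb$db
  dX <- bf$dX
  dX[rev_idx, ] <- dX[rev_idx, ] + bb$dX
  g$vemb <- matrix(0, cfg$vocab_size, cfg$emb_dim)
  agg <- rowsum(dX, group = ids)
  g$vemb[as.integer(rownames(agg)), ] <- agg
  list(loss = loss, grads = g)
}

#' Train the conditional text VAE
#'
#' Adam on the negative ELBO with linear KL annealing from 0 to 1 over the
#' first third of training. Trains only on the corpus it is given — callers
#' pass the training split so augmented records never leak into validation
#' or test data.
#'
#' @param corpus Corpus data.frame (typically the training split).
#' @param tokenizer Tokenizer handle (its vocabulary sizes the decoder).
#' @param config A [vae_config()]; `vocab_size` is overridden to match the
#'   tokenizer.
#' @param epochs,lr Optimization settings.
#' @param verbose Print per-epoch losses.
#' @return A trained `phqgad_vae` (with `tokenizer` attached).
#' @export
train_vae <- function(corpus, tokenizer, config = vae_config(),
                      epochs = 15L, lr = 3e-3, verbose = FALSE) {
  config$vocab_size <- tokenizer$vocab_size
  vae <- init_vae(config)
  with_seed(config$seed, {
    ids_list <- lapply(corpus$text, function(tx) {
      ids <- tokenize(tx, tokenizer, config$max_len)$token_ids
      ids[-1L]  # VAE reconstructs the raw token sequence, no [CLS]
    })
    keep <- vapply(ids_list, length, integer(1)) >= 1L
    ids_list <- ids_list[keep]
    ybins <- cbind(as.integer(severity_bin(corpus$phq9[keep])),
                   as.integer(severity_bin(corpus$gad7[keep])))
    n <- length(ids_list)
    # inverse-frequency oversampling of joint strata so the conditional
    # embeddings of rare severity combinations get trained too
    stratum <- interaction(ybins[, 1L], ybins[, 2L], drop = TRUE)
    inv_freq <- 1 / as.numeric(table(stratum))[as.integer(stratum)]
    samp_w <- inv_freq / sum(inv_freq)
    opt <- NULL
    total_steps <- epochs * n
    anneal_steps <- max(1, floor(total_steps / 3))
    step <- 0L
    m <- NULL; v <- NULL
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n, n, replace = TRUE, prob = samp_w)
      ep_loss <- 0
      for (i in perm) {
        step <- step + 1L
        klw <- min(1, step / anneal_steps)
        sg <- vae_sample_grad(vae, ids_list[[i]], ybins[i, ], klw)
        ep_loss <- ep_loss + sg$loss$total
        if (is.null(m)) {
          m <- lapply(sg$grads, function(x) x * 0)
          v <- m
        }
        for (nm in names(sg$grads)) {
          gg <- sg$grads[[nm]]
          m[[nm]] <- 0.9 * m[[nm]] + 0.1 * gg
          v[[nm]] <- 0.999 * v[[nm]] + 0.001 * gg^2
          mh <- m[[nm]] / (1 - 0.9^step)
          vh <- v[[nm]] / (1 - 0.999^step)
          vae$params[[nm]] <- vae$params[[nm]] - lr * mh / (sqrt(vh) + 1e-8)
        }
      }
      if (verbose) message(sprintf("VAE epoch %d loss %.3f", ep, ep_loss / n))
    }
    vae$tokenizer <- tokenizer
    vae
  })
}

# ---- generation-quality mechanisms ---------------------------------------

token_counts <- function(text, mode = "whitespace") {
  table(segment_text(text, mode))
}

#' Bag-of-token cosine similarity
#'
#' Default semantic-similarity function for the acceptance filters: cosine
#' over token-count vectors. Production deployments can plug in a sentence
#' embedding model instead.
#'
#' @param a,b Texts.
#' @param mode Segmentation mode.
#' @return Similarity in `[0, 1]` (1 for identical bags).
#' @export
cosine_similarity <- function(a, b, mode = "whitespace") {
  ta <- token_counts(a, mode); tb <- token_counts(b, mode)
  toks <- union(names(ta), names(tb))
  va <- as.numeric(ta[toks]); va[is.na(va)] <- 0
  vb <- as.numeric(tb[toks]); vb[is.na(vb)] <- 0
  den <- sqrt(sum(va^2)) * sqrt(sum(vb^2))
  if (den == 0) return(0)
  sum(va * vb) / den
}

#' Bag-of-words label-consistency classifier
#'
#' Trains a per-task multinomial naive-Bayes model (add-one smoothing) on
#' bag-of-words counts per severity bin. Used by the acceptance filters to
#' verify that a generated text still reads as its target severity.
#'
#' @param corpus Training corpus.
#' @param tokenizer Tokenizer handle.
#' @return A classifier function `f(text) -> list(phq_bin, gad_bin)`
#'   (integer bins 1-3).
#' @export
train_consistency_classifier <- function(corpus, tokenizer) {
  vocab <- names(tokenizer$vocab)
  bow <- function(text) {
    tc <- token_counts(text, tokenizer$mode)
    v <- as.numeric(tc[vocab]); v[is.na(v)] <- 0
    v
  }
  X <- t(vapply(corpus$text, bow, numeric(length(vocab))))
  nb_fit <- function(bins) {
    bins <- as.integer(bins)
    # log emission probabilities with add-one smoothing, log priors
    loglik <- t(vapply(1:3, function(b) {
      sel <- bins == b
      counts <- if (any(sel)) colSums(X[sel, , drop = FALSE]) else {
        rep(0, ncol(X))
      }
      log((counts + 1) / sum(counts + 1))
    }, numeric(ncol(X))))
    logprior <- log((tabulate(bins, 3L) + 1) / (length(bins) + 3))
    list(loglik = loglik, logprior = logprior)
  }
  nb_phq <- nb_fit(severity_bin(corpus$phq9))
  nb_gad <- nb_fit(severity_bin(corpus$gad7))
  nb_predict <- function(v, fit) {
    which.max(fit$logprior + as.numeric(fit$loglik %*% v))
  }
  function(text) {
    v <- bow(text)
    list(phq_bin = nb_predict(v, nb_phq), gad_bin = nb_predict(v, nb_gad))
  }
}

normalized_edit_distance <- function(a, b) {
  d <- utils::adist(a, b)[1L, 1L]
  d / max(nchar(a), nchar(b), 1L)
}

default_fluency <- function(tokenizer) {
  function(text) {
    toks <- segment_text(text, tokenizer$mode)
    if (length(toks) == 0L) return(0)
    mean(toks %in% names(tokenizer$vocab))
  }
}

#' Apply the four generation-quality filters to a candidate
#'
#' Mechanisms: (1) semantic similarity to the source strictly above the
#' threshold; (2) a consistency classifier's predicted severity pair equals
#' the target condition; (3) diversity — normalized edit distance from the
#' source and from previously accepted candidates at least `min_diversity`;
#' (4) fluency score at or above the floor. A candidate is accepted iff
#' every supplied filter passes; a filter whose model is missing reports
#' `NA` ("skipped") and is excluded from the decision.
#'
#' @param original Source text the candidate was generated from.
#' @param generated Candidate text.
#' @param y Target condition (integer severity pair).
#' @param config A [vae_config()] (thresholds).
#' @param similarity_fn,consistency_clf,fluency_fn Pluggable models; `NULL`
#'   skips that mechanism.
#' @param accepted_texts Character vector of previously accepted candidates.
#' @return List with per-mechanism logicals (`similarity`, `consistency`,
#'   `diversity`, `fluency`; `NA` = skipped), `accept`, and the raw
#'   `similarity_score`.
#' @export
filter_generated <- function(original, generated, y, config,
                             similarity_fn = cosine_similarity,
                             consistency_clf = NULL,
                             fluency_fn = NULL,
                             accepted_texts = character(0)) {
  res <- list(similarity = NA, consistency = NA, diversity = NA,
              fluency = NA, similarity_score = NA_real_)
  if (!is.null(similarity_fn)) {
    s <- similarity_fn(original, generated)
    res$similarity_score <- s
    res$similarity <- s > config$similarity_threshold  # strictly above
  }
  if (!is.null(consistency_clf)) {
    pred <- consistency_clf(generated)
    res$consistency <- (pred$phq_bin == y[1L]) && (pred$gad_bin == y[2L])
  }
  dists <- vapply(c(original, accepted_texts), normalized_edit_distance,
                  numeric(1), b = generated)
  res$diversity <- all(dists >= config$min_diversity)
  if (!is.null(fluency_fn)) {
    res$fluency <- nzchar(trimws(generated)) &&
      fluency_fn(generated) >= config$fluency_floor
  } else {
    res$fluency <- NA
  }
  checks <- unlist(res[c("similarity", "consistency", "diversity", "fluency")])
  res$accept <- all(checks[!is.na(checks)])
  res
}

#' Class balance of a corpus
#'
#' Normalized entropy of the joint severity-stratum distribution:
#' `H(p) / log(K)` over the `K` occupied strata. 1 for perfectly uniform
#' strata, 0 when a single stratum holds everything.
#'
#' @param corpus Corpus data.frame.
#' @return Balance in `[0, 1]`.
#' @export
class_balance <- function(corpus) {
  stopifnot(nrow(corpus) > 0L)
  strata <- interaction(severity_bin(corpus$phq9), severity_bin(corpus$gad7),
                        drop = TRUE)
  p <- as.numeric(table(strata)) / nrow(corpus)
  p <- p[p > 0]
  if (length(p) <= 1L) return(0)
  -sum(p * log(p)) / log(length(p))
}

#' Augment a corpus toward class balance
#'
#' Generates VAE candidates preferentially for under-represented joint
#' severity strata until the accepted count reaches
#' `(target_multiplier - 1) * n` or the candidate budget is exhausted.
#' Originals are always retained unmodified (superset property); generated
#' records carry `synthetic = TRUE` and provenance of their source record.
#'
#' @param corpus Corpus to augment (pass the *training split* — the VAE is
#'   trained here on that corpus only).
#' @param target_multiplier Final size as a multiple of the original
#'   (default 2.0, i.e. +100%).
#' @param config A [vae_config()].
#' @param vae Optionally a pre-trained `phqgad_vae` (skips training).
#' @param tokenizer Tokenizer; built from `corpus` when `NULL`.
#' @param filters `"all"` for the four quality mechanisms, `"none"` for
#'   pass-through acceptance.
#' @param budget_factor Candidate budget as a multiple of the needed count.
#' @param vae_epochs Training epochs for the in-pipeline VAE.
#' @return List with `corpus` (augmented) and `report`
#'   (an augmentation-report list).
#' @export
augment_to_balance <- function(corpus, target_multiplier = 2.0,
                               config = vae_config(), vae = NULL,
                               tokenizer = NULL, filters = c("all", "none"),
                               budget_factor = 20, vae_epochs = 25L) {
  filters <- match.arg(filters)
  stopifnot(target_multiplier >= 1)
  n_orig <- nrow(corpus)
  need <- round((target_multiplier - 1) * n_orig)
  balance_before <- class_balance(corpus)
  if (need == 0L) {
    return(list(corpus = corpus, report = list(
      n_original = n_orig, n_generated = 0L,
      n_passed = c(similarity = 0L, consistency = 0L, diversity = 0L,
                   fluency = 0L),
      class_balance_before = balance_before,
      class_balance_after = balance_before,
      mean_semantic_similarity = NA_real_,
      label_consistency_rate = NA_real_)))
  }
  if (is.null(tokenizer)) tokenizer <- build_tokenizer(corpus$text)
  config$vocab_size <- tokenizer$vocab_size
  if (is.null(vae)) {
    vae <- train_vae(corpus, tokenizer, config, epochs = vae_epochs)
  }
  use_filters <- filters == "all"
  clf <- if (use_filters) train_consistency_classifier(corpus, tokenizer)
  flu <- if (use_filters) default_fluency(tokenizer)
  with_seed(config$seed + 1L, {
    bins <- interaction(severity_bin(corpus$phq9), severity_bin(corpus$gad7),
                        drop = TRUE)
    stratum_names <- levels(bins)
    counts <- as.numeric(table(bins))
    names(counts) <- stratum_names
    members <- split(seq_len(n_orig), bins)
    accepted <- list()
    accepted_texts_by_stratum <- stats::setNames(
      vector("list", length(stratum_names)), stratum_names)
    n_generated <- 0L
    n_passed <- c(similarity = 0L, consistency = 0L, diversity = 0L,
                  fluency = 0L)
    sim_scores <- numeric(0)
    cons_flags <- logical(0)
    budget <- ceiling(budget_factor * need)
    join_char <- if (tokenizer$mode == "whitespace") " " else ""
    while (length(accepted) < need && n_generated < budget) {
      # deficit-weighted target choice: attempts spread over every
      # under-represented stratum instead of hammering the single rarest
      deficit <- pmax(max(counts) - counts, 0)
      target <- if (sum(deficit) > 0) {
        sample(names(counts), 1L, prob = deficit)
      } else names(counts)[which.min(counts)]
      src_idx <- members[[target]][sample.int(length(members[[target]]), 1L)]
      src <- corpus[src_idx, ]
      y <- c(as.integer(severity_bin(src$phq9)),
             as.integer(severity_bin(src$gad7)))
      ids <- tokenize(src$text, tokenizer, config$max_len)$token_ids[-1L]
      code <- encode_posterior(ids, vae)
      z <- reparameterize(code)
      dec <- vae_decode(z, y, vae, len = length(ids))
      vocab_rev <- c("[UNK]", "[CLS]", names(tokenizer$vocab))
      gen_text <- paste(vocab_rev[dec$ids], collapse = join_char)
      n_generated <- n_generated + 1L
      if (use_filters) {
        fr <- filter_generated(src$text, gen_text, y, config,
                               similarity_fn = function(a, b) {
                                 cosine_similarity(a, b, tokenizer$mode)
                               },
                               consistency_clf = clf, fluency_fn = flu,
                               accepted_texts =
                                 accepted_texts_by_stratum[[target]] %||%
                                 character(0))
        for (nm in names(n_passed)) {
          if (isTRUE(fr[[nm]])) n_passed[nm] <- n_passed[nm] + 1L
        }
        sim_scores <- c(sim_scores, fr$similarity_score)
        cons_flags <- c(cons_flags, isTRUE(fr$consistency))
        if (!fr$accept) next
      } else {
        n_passed <- n_passed + 1L
      }
      rec <- src
      rec$record_id <- sprintf("%s_aug%05d", src$record_id,
                               length(accepted) + 1L)
      rec$text <- gen_text
      rec$synthetic <- TRUE
      attr(rec, "source_record_id") <- src$record_id
      accepted[[length(accepted) + 1L]] <- rec
      accepted_texts_by_stratum[[target]] <-
        c(accepted_texts_by_stratum[[target]], gen_text)
      counts[target] <- counts[target] + 1
    }
    if (length(accepted) < need) {
      warning("augmentation budget exhausted: accepted ", length(accepted),
              " of ", need, " requested samples")
    }
    aug <- if (length(accepted) > 0L) {
      rbind(corpus, do.call(rbind, accepted))
    } else corpus
    rownames(aug) <- NULL
    report <- list(
      n_original = n_orig,
      n_generated = n_generated,
      n_accepted = length(accepted),
      n_passed = n_passed,
      class_balance_before = balance_before,
      class_balance_after = class_balance(aug),
      mean_semantic_similarity = if (length(sim_scores)) {
        mean(sim_scores, na.rm = TRUE)
      } else NA_real_,
      label_consistency_rate = if (length(cons_flags)) {
        mean(cons_flags)
      } else NA_real_
    )
    list(corpus = aug, report = report)
  })
}

#' Expand a test set by augmentation (explicitly labeled operation)
#'
#' Test-set expansion is deliberately separate from training-split
#' augmentation so the leakage guard is visible at the call site: the VAE
#' passed here must have been trained on the training split.
#'
#' @param test_corpus The held-out test corpus.
#' @param vae A `phqgad_vae` trained on the *training* split.
#' @param multiplier Expansion factor (default 1 = off).
#' @param ... Passed to [augment_to_balance()].
#' @return Expanded corpus plus report.
#' @export
expand_test_set <- function(test_corpus, vae, multiplier = 1.0, ...) {
  augment_to_balance(test_corpus, target_multiplier = multiplier, vae = vae,
                     ...)
}
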