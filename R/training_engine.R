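# Training protocol: cosine-annealed AdamW, the regularization bundle
# (dropout, stochastic depth, label smoothing, gradient noise, weight decay),
# per-step EMA parameter smoothing, early stopping on validation screening
# F1, and weighted-average ensembling.

#' Training configuration
#'
#' Shipped defaults mirror the reference protocol: 35 epochs, batch size 58,
#' cosine learning-rate annealing from 1e-5 to 1e-6, AdamW weight decay 0.03,
#' dropout 0.5, stochastic depth 0.1, label smoothing 0.1, gradient noise
#' 1e-5, EMA decay 0.999, early-stop patience 3. Desk-scale runs on tiny
#' randomly initialized encoders typically override `lr_max`/`lr_min` upward
#' and `dropout` downward, since the defaults are fine-tuning rates for a
#' large pretrained encoder.
#'
#' @param epochs Total training epochs `T`.
#' @param batch_size Mini-batch size.
#' @param lr_max,lr_min Cosine schedule endpoints.
#' @param patience Early-stop patience in epochs.
#' @param dropout Dropout probability (MLP layers and attention layers).
#' @param weight_decay Decoupled AdamW weight-decay coefficient.
#' @param stochastic_depth_rate Per-layer skip probability during training.
#' @param label_smoothing Classification label-smoothing factor.
#' @param grad_noise_scale Standard deviation of Gaussian gradient noise.
#' @param ema_decay EMA smoothing coefficient (`beta`), in `[0, 1)`.
#' @param seed Run seed; every RNG stream (init, batching, dropout, depth,
#'   noise) derives from it.
#' @return A `phqgad_train_config` list.
#' @export
train_config <- function(epochs = 35L, batch_size = 58L, lr_max = 1e-5,
                         lr_min = 1e-6, patience = 3L, dropout = 0.5,
                         weight_decay = 0.03, stochastic_depth_rate = 0.1,
                         label_smoothing = 0.1, grad_noise_scale = 1e-5,
                         ema_decay = 0.999, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr_min <= lr_max,
            patience >= 1L, dropout >= 0, dropout < 1,
            stochastic_depth_rate >= 0, stochastic_depth_rate < 1,
            ema_decay >= 0, ema_decay < 1, grad_noise_scale >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_max = lr_max, lr_min = lr_min,
                 patience = as.integer(patience), dropout = dropout,
                 weight_decay = weight_decay,
                 stochastic_depth_rate = stochastic_depth_rate,
                 label_smoothing = label_smoothing,
                 grad_noise_scale = grad_noise_scale,
                 ema_decay = ema_decay, seed = as.integer(seed)),
            class = "phqgad_train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr_min + (lr_max - lr_min) / 2 * (1 + cos(t * pi / T))`, indexed by
#' epoch: `t = 0` gives `lr_max`, `t = T` gives `lr_min`.
#'
#' @param t Current epoch (0-based), `0 <= t <= T`.
#' @param config A [train_config()] (uses `lr_max`, `lr_min`, `epochs`).
#' @return Learning-rate scalar.
#' @export
cosine_lr <- function(t, config) {
  T_ <- config$epochs
  if (any(t < 0 | t > T_)) stop("cosine_lr: t out of [0, T]")
  config$lr_min + 0.5 * (config$lr_max - config$lr_min) *
    (1 + cos(t * pi / T_))
}

#' Inject Gaussian gradient noise
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation `scale` to
#' every gradient entry.
#'
#' @param grads Flat named list of gradient arrays.
#' @param scale Noise standard deviation (0 = identity).
#' @return Perturbed gradient list.
#' @export
inject_gradient_noise <- function(grads, scale) {
  stopifnot(scale >= 0)
  if (scale == 0) return(grads)
  lapply(grads, function(g) g + stats::rnorm(length(g), sd = scale))
}

#' Initialize an EMA state from current parameters
#'
#' @param params Flat named parameter list.
#' @param decay Smoothing coefficient `beta` (default 0.999).
#' @return A `phqgad_ema` list with `shadow`, `decay`, `step_count`.
#' @export
ema_init <- function(params, decay = 0.999) {
  structure(list(shadow = params, decay = decay, step_count = 0L),
            class = "phqgad_ema")
}

#' One EMA update step
#'
#' Coordinate-wise `theta_EMA <- beta * theta_EMA + (1 - beta) * theta`.
#' Shadow coordinates stay inside the running min/max of their history.
#'
#' @param state A `phqgad_ema` state.
#' @param current Current parameter list (same shapes).
#' @return Updated state.
#' @export
ema_update <- function(state, current) {
  if (!identical(lapply(state$shadow, length), lapply(current, length))) {
    stop("ema_update: parameter shape mismatch")
  }
  b <- state$decay
  state$shadow <- Map(function(s, c) b * s + (1 - b) * c,
                      state$shadow, current)
  state$step_count <- state$step_count + 1L
  state
}

#' Stochastic-depth layer mask
#'
#' During training each eligible layer is independently skipped
#' (residual-only pass) with probability `rate`; evaluation always runs the
#' full depth.
#'
#' @param n_layers Number of eligible layers.
#' @param rate Skip probability in `[0, 1)`.
#' @param training Logical; `FALSE` returns an all-active mask.
#' @return Logical vector, `TRUE` = skip.
#' @export
stochastic_depth_mask <- function(n_layers, rate, training = TRUE) {
  stopifnot(rate >= 0, rate < 1)
  if (!training || rate == 0) return(rep(FALSE, n_layers))
  stats::runif(n_layers) < rate
}

#' Early-stopping rule
#'
#' Stops when the monitored metric (higher is better) has not improved over
#' its running best for `patience` consecutive epochs.
#'
#' @param metric Numeric vector of per-epoch validation metric values.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return `TRUE` if training should stop after the last recorded epoch.
#' @export
early_stop <- function(metric, patience) {
  stopifnot(length(metric) >= 1L, patience >= 1L)
  best_at <- which.max(metric)
  (length(metric) - best_at) >= patience
}

# AdamW update, decoupled weight decay on weight matrices (not biases or
# layer-norm parameters).
adamw_init <- function(params) {
  zeros <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else rep(0, length(p))
  })
  decay_ok <- grepl("(_W[a-z0-9]*$|^emb_|_W1$|_W2$)", names(params)) &
    vapply(params, is.matrix, logical(1))
  list(m = zeros, v = zeros, t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
       decay_ok = stats::setNames(decay_ok, names(params)))
}

adamw_step <- function(opt, params, grads, lr, weight_decay) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    wd <- if (opt$decay_ok[[nm]]) weight_decay * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - lr * (step + wd)
  }
  list(opt = opt, params = params)
}

# Binary screening F1 (positive class = predicted severe, i.e. score >= 10)
# for early stopping and reporting.
screening_f1 <- function(pred_class, true_score) {
  pred_pos <- pred_class == "severe"
  true_pos <- true_score >= 10
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

validation_mean_f1 <- function(model, ids_list, phq, gad,
                               monitor = "mean", batch_size = 128L) {
  n <- length(ids_list)
  pc <- character(n); gc_ <- character(n)
  for (k in seq_len(ceiling(n / batch_size))) {
    sel <- ((k - 1L) * batch_size + 1L):min(k * batch_size, n)
    fw <- model_forward(model, ids_list[sel], training = FALSE)
    pc[sel] <- .SEVERITY_LEVELS[max.col(fw$p_phq_cls)]
    gc_[sel] <- .SEVERITY_LEVELS[max.col(fw$p_gad_cls)]
  }
  switch(monitor,
         phq = screening_f1(pc, phq),
         gad = screening_f1(gc_, gad),
         mean(c(screening_f1(pc, phq), screening_f1(gc_, gad))))
}

#' Train the multitask model
#'
#' Full protocol: per-epoch cosine learning-rate schedule, AdamW with
#' decoupled weight decay, dropout, stochastic depth, label smoothing,
#' gradient noise, per-step EMA tracking, early stopping on the validation
#' mean binary screening F1 (average of the PHQ-9 and GAD-7 positive-class
#' F1 at the >= 10 threshold), and best-epoch checkpoint retention.
#'
#' @param split A `phqgad_split` (train/validation parts used).
#' @param model A freshly initialized `phqgad_model` (or `NULL` to
#'   initialize from `spec`).
#' @param tokenizer Tokenizer handle; built from the training texts when
#'   `NULL`.
#' @param weights A [loss_weights()] bundle. Class weights are computed from
#'   the training labels when left at their uniform default.
#' @param config A [train_config()].
#' @param spec An [encoder_spec()] used when `model` is `NULL`.
#' @param verbose Print one line per epoch.
#' @param monitor_task Validation metric to monitor: `"mean"` of both tasks
#'   (default) or a single task's screening F1 — single-task runs in the
#'   ablation harness monitor their own task only.
#' @return List with `model` (best-validation checkpoint), `ema`
#'   (`phqgad_ema`), `ema_model` (model carrying EMA shadow parameters),
#'   `history` (per-epoch data.frame), `tokenizer`, `weights`.
#' @export
train_multitask <- function(split, model = NULL, tokenizer = NULL,
                            weights = loss_weights(), config = train_config(),
                            spec = NULL, verbose = FALSE,
                            monitor_task = c("mean", "phq", "gad")) {
  monitor_task <- match.arg(monitor_task)
  stopifnot(nrow(split$train) > 0L, nrow(split$validation) > 0L)
  with_seed(config$seed, {
    if (is.null(tokenizer)) {
      tokenizer <- build_tokenizer(split$train$text)
    }
    if (is.null(model)) {
      spec <- spec %||% encoder_spec("tiny_random",
                                     vocab_size = tokenizer$vocab_size)
      model <- init_multitask_model(spec, seed = config$seed)
    }
    # fill class weights from the training labels if left uniform
    if (all(weights$class_weights_phq == 1)) {
      weights$class_weights_phq <-
        compute_class_weights(severity_bin(split$train$phq9))
    }
    if (all(weights$class_weights_gad == 1)) {
      weights$class_weights_gad <-
        compute_class_weights(severity_bin(split$train$gad7))
    }
    weights$label_smoothing <- config$label_smoothing
    tok_ids <- function(df) lapply(df$text, function(tx) {
      tokenize(tx, tokenizer, model$spec$max_len)$token_ids
    })
    train_ids <- tok_ids(split$train)
    val_ids <- tok_ids(split$validation)
    n <- length(train_ids)
    opt <- adamw_init(model$params)
    ema <- ema_init(model$params, config$ema_decay)
    hist <- list()
    best_f1 <- -Inf
    best_params <- model$params
    best_epoch <- 0L
    f1_track <- numeric(0)
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(epoch - 1L, config)
      perm <- sample.int(n)
      ep_tot <- 0; ep_reg_p <- 0; ep_reg_g <- 0; nb <- 0L
      for (k in seq_len(ceiling(n / config$batch_size))) {
        sel <- perm[((k - 1L) * config$batch_size + 1L):
                      min(k * config$batch_size, n)]
        lg <- multitask_loss_grad(
          model, train_ids[sel],
          split$train$phq9[sel], split$train$gad7[sel],
          weights = weights, training = TRUE,
          dropout = config$dropout,
          depth_rate = config$stochastic_depth_rate)
        if (!is.finite(lg$total)) {
          stop("training diverged: non-finite loss at epoch ", epoch)
        }
        grads <- inject_gradient_noise(lg$grads, config$grad_noise_scale)
        st <- adamw_step(opt, model$params, grads, lr, config$weight_decay)
        opt <- st$opt
        model$params <- st$params
        ema <- ema_update(ema, model$params)
        ep_tot <- ep_tot + lg$total
        ep_reg_p <- ep_reg_p +
          mean((lg$forward$y_phq_reg - split$train$phq9[sel])^2)
        ep_reg_g <- ep_reg_g +
          mean((lg$forward$y_gad_reg - split$train$gad7[sel])^2)
        nb <- nb + 1L
      }
      val_f1 <- validation_mean_f1(model, val_ids, split$validation$phq9,
                                   split$validation$gad7,
                                   monitor = monitor_task)
      f1_track <- c(f1_track, val_f1)
      improved <- val_f1 > best_f1
      if (improved) {
        best_f1 <- val_f1
        best_params <- model$params
        best_epoch <- epoch
      }
      stop_now <- early_stop(f1_track, config$patience)
      hist[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, train_total_loss = ep_tot / nb,
        train_mse_phq = ep_reg_p / nb, train_mse_gad = ep_reg_g / nb,
        val_mean_f1 = val_f1, improved = improved,
        early_stop = stop_now, best_epoch = best_epoch)
      if (verbose) {
        message(sprintf("epoch %2d lr %.2e loss %.4f val F1 %.3f%s",
                        epoch, lr, ep_tot / nb, val_f1,
                        if (stop_now) " [stop]" else ""))
      }
      if (stop_now) break
    }
    best_model <- model
    best_model$params <- best_params
    ema_model <- model
    ema_model$params <- ema$shadow
    list(model = best_model, ema = ema, ema_model = ema_model,
         history = do.call(rbind, hist), tokenizer = tokenizer,
         weights = weights, config = config, best_epoch = best_epoch)
  })
}

#' Weighted-average ensemble prediction
#'
#' Averages regression outputs with the given weights; classification
#' probability vectors are averaged with the same weights and renormalized.
#'
#' @param models List of trained `phqgad_model`s.
#' @param corpus Corpus data.frame to predict on.
#' @param tokenizer Tokenizer handle shared by the members.
#' @param weights Non-negative member weights summing to 1 (default
#'   uniform).
#' @return Prediction data.frame in the [model_predict()] layout.
#' @export
ensemble_predict <- function(models, corpus, tokenizer, weights = NULL) {
  if (length(models) == 0L) stop("ensemble_predict: empty model list")
  k <- length(models)
  weights <- weights %||% rep(1 / k, k)
  stopifnot(length(weights) == k, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8)
  preds <- lapply(models, model_predict, corpus = corpus,
                  tokenizer = tokenizer, clamp = FALSE)
  prob_cols <- c("p_phq_mild", "p_phq_moderate", "p_phq_severe",
                 "p_gad_mild", "p_gad_moderate", "p_gad_severe")
  out <- preds[[1]]
  out$phq9_pred <- Reduce(`+`, Map(function(p, w) w * p$phq9_pred,
                                   preds, weights))
  out$gad7_pred <- Reduce(`+`, Map(function(p, w) w * p$gad7_pred,
                                   preds, weights))
  for (cc in prob_cols) {
    out[[cc]] <- Reduce(`+`, Map(function(p, w) w * p[[cc]], preds, weights))
  }
  phq_p <- as.matrix(out[, prob_cols[1:3]])
  gad_p <- as.matrix(out[, prob_cols[4:6]])
  phq_p <- phq_p / rowSums(phq_p)
  gad_p <- gad_p / rowSums(gad_p)
  out[, prob_cols[1:3]] <- phq_p
  out[, prob_cols[4:6]] <- gad_p
  out$phq9_class <- .SEVERITY_LEVELS[max.col(phq_p)]
  out$gad7_class <- .SEVERITY_LEVELS[max.col(gad_p)]
  out
}

#' Save / load a model checkpoint
#'
#' The parameter archive is a serialized R object; a JSON sidecar records
#' the encoder spec and a hash of the training configuration.
#'
#' @param result A training result (or bare `phqgad_model`).
#' @param path Checkpoint path (`.rds`); sidecar written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(result, path) {
  model <- if (inherits(result, "phqgad_model")) result else result$model
  saveRDS(result, path)
  sidecar <- list(
    spec = unclass(model$spec),
    n_params = sum(vapply(model$params, length, numeric(1))),
    config_hash = if (!is.null(result$config)) {
      sum(utils::head(utf8ToInt(paste(
        names(result$config), unlist(result$config), collapse = ",")), 1e4))
    } else NA
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
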