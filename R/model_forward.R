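# Batched forward and backward passes for the multitask model.
#
# A batch is a list of integer token-id vectors of varying length. Sequences
# are packed into a single (B * Lb) x d matrix (Lb = longest sequence in the
# batch); position-wise operations (projections, layer norm, feed-forward,
# fusion MLP, heads) run as single matrix products over all rows, while the
# L x L attention products run per sample on the real (non-padding) rows.

row_index <- function(b, Lb) ((b - 1L) * Lb + 1L):(b * Lb)

drop_mask <- function(dim1, dim2, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
}

apply_drop <- function(X, mask) if (is.null(mask)) X else X * mask

# Multi-head self-attention block with residual connection and layer norm.
mha_block_forward <- function(p, prefix, H, real_rows_list, h, training,
                              dropout) {
  d <- ncol(H)
  d_k <- d %/% h
  Wq <- p[[paste0(prefix, "_Wq")]]; Wk <- p[[paste0(prefix, "_Wk")]]
  Wv <- p[[paste0(prefix, "_Wv")]]; Wo <- p[[paste0(prefix, "_Wo")]]
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  O <- matrix(0, nrow(H), d)
  A_all <- vector("list", length(real_rows_list))
  for (b in seq_along(real_rows_list)) {
    rows <- real_rows_list[[b]]
    A_b <- vector("list", h)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * d_k + 1L):(i * d_k)
      A <- softmax(Q[rows, cols, drop = FALSE] %*%
                     t(K[rows, cols, drop = FALSE]) / sqrt(d_k))
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      A_b[[i]] <- A
    }
    A_all[[b]] <- A_b
  }
  O2 <- O %*% Wo
  dmask <- if (training && dropout > 0) drop_mask(nrow(H), d, dropout) else NULL
  ln <- layernorm_forward(H + apply_drop(O2, dmask),
                          p[[paste0(prefix, "_ln1_g")]],
                          p[[paste0(prefix, "_ln1_b")]])
  list(Y = ln$Y,
       cache = list(H = H, Q = Q, K = K, V = V, O = O, A = A_all,
                    dmask = dmask, ln = ln, prefix = prefix, h = h,
                    real_rows_list = real_rows_list))
}

mha_block_backward <- function(p, cache, dY) {
  prefix <- cache$prefix
  h <- cache$h
  d <- ncol(cache$H)
  d_k <- d %/% h
  g <- p[[paste0(prefix, "_ln1_g")]]
  lb <- layernorm_backward(dY, cache$ln, g)
  dZ <- lb$dX
  dO2 <- apply_drop(dZ, cache$dmask)
  Wo <- p[[paste0(prefix, "_Wo")]]
  dWo <- crossprod(cache$O, dO2)
  dO <- dO2 %*% t(Wo)
  dQ <- matrix(0, nrow(dY), d); dK <- dQ; dV <- dQ
  for (b in seq_along(cache$real_rows_list)) {
    rows <- cache$real_rows_list[[b]]
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * d_k + 1L):(i * d_k)
      A <- cache$A[[b]][[i]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- dOb %*% t(Vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(d_k)
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE]
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE])
    }
  }
  H <- cache$H
  grads <- stats::setNames(
    list(crossprod(H, dQ), crossprod(H, dK), crossprod(H, dV), dWo,
         lb$dg, lb$db),
    paste0(prefix, c("_Wq", "_Wk", "_Wv", "_Wo", "_ln1_g", "_ln1_b")))
  dH <- dZ + dQ %*% t(p[[paste0(prefix, "_Wq")]]) +
    dK %*% t(p[[paste0(prefix, "_Wk")]]) +
    dV %*% t(p[[paste0(prefix, "_Wv")]])
  list(dH = dH, grads = grads)
}

ff_block_forward <- function(p, prefix, H, training, dropout) {
  W1 <- p[[paste0(prefix, "_ff_W1")]]; b1 <- p[[paste0(prefix, "_ff_b1")]]
  W2 <- p[[paste0(prefix, "_ff_W2")]]; b2 <- p[[paste0(prefix, "_ff_b2")]]
  Z1 <- sweep(H %*% W1, 2L, b1, `+`)
  F1 <- pmax(Z1, 0)
  dmask <- if (training && dropout > 0) {
    drop_mask(nrow(F1), ncol(F1), dropout)
  } else NULL
  Fd <- apply_drop(F1, dmask)
  F2 <- sweep(Fd %*% W2, 2L, b2, `+`)
  ln <- layernorm_forward(H + F2, p[[paste0(prefix, "_ln2_g")]],
                          p[[paste0(prefix, "_ln2_b")]])
  list(Y = ln$Y, cache = list(H = H, F1 = F1, Fd = Fd, dmask = dmask,
                              ln = ln, prefix = prefix))
}

ff_block_backward <- function(p, cache, dY) {
  prefix <- cache$prefix
  lb <- layernorm_backward(dY, cache$ln,
                           p[[paste0(prefix, "_ln2_g")]])
  dZ <- lb$dX
  W2 <- p[[paste0(prefix, "_ff_W2")]]
  dW2 <- crossprod(cache$Fd, dZ)
  db2 <- colSums(dZ)
  dFd <- dZ %*% t(W2)
  dF1 <- apply_drop(dFd, cache$dmask) * (cache$F1 > 0)
  dW1 <- crossprod(cache$H, dF1)
  db1 <- colSums(dF1)
  dH <- dZ + dF1 %*% t(p[[paste0(prefix, "_ff_W1")]])
  grads <- stats::setNames(
    list(dW1, db1, dW2, db2, lb$dg, lb$db),
    paste0(prefix, c("_ff_W1", "_ff_b1", "_ff_W2", "_ff_b2",
                     "_ln2_g", "_ln2_b")))
  list(dH = dH, grads = grads)
}

#' Encode a tokenized sample
#'
#' Runs the encoder stack (and the extra self-attention block when the spec
#' enables it) on a single sample and returns the per-token hidden states.
#' Evaluation mode: no dropout, no stochastic depth.
#'
#' @param sample A tokenized sample from [tokenize()] (or a bare integer
#'   vector of token ids).
#' @param model A `phqgad_model`.
#' @return An L x d matrix of hidden states.
#' @export
encode <- function(sample, model) {
  ids <- if (is.list(sample)) sample$token_ids else as.integer(sample)
  if (length(ids) > model$spec$max_len) {
    stop("sequence length ", length(ids), " exceeds max_len ",
         model$spec$max_len, " (truncate in tokenize())")
  }
  fw <- model_forward(model, list(ids), training = FALSE)
  fw$hidden[[1]]
}

#' Forward pass over a batch
#'
#' @param model A `phqgad_model`.
#' @param ids_list List of integer token-id vectors.
#' @param training Logical; enables dropout and stochastic depth.
#' @param dropout Dropout probability (used only when `training`).
#' @param depth_rate Stochastic-depth skip probability per encoder layer
#'   (used only when `training`).
#' @param keep_cache Keep intermediates for [model_backward()].
#' @return List with regression predictions (`y_phq_reg`, `y_gad_reg`),
#'   class probabilities (`p_phq_cls`, `p_gad_cls`, rows summing to 1),
#'   logits, fused features, per-sample `hidden` states, and `cache`.
#' @export
model_forward <- function(model, ids_list, training = FALSE, dropout = 0,
                          depth_rate = 0, keep_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  d <- spec$hidden_dim
  B <- length(ids_list)
  lens <- vapply(ids_list, length, integer(1))
  stopifnot(all(lens >= 1L), all(lens <= spec$max_len))
  Lb <- max(lens)
  H <- matrix(0, B * Lb, d)
  real_rows_list <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- row_index(b, Lb)[seq_len(lens[b])]
    real_rows_list[[b]] <- rows
    H[rows, ] <- p$emb_tok[ids_list[[b]], , drop = FALSE] +
      p$emb_pos[seq_len(lens[b]), , drop = FALSE]
  }
  skip <- if (training && depth_rate > 0) {
    stats::runif(spec$n_layers) < depth_rate
  } else rep(FALSE, spec$n_layers)
  layer_caches <- vector("list", spec$n_layers)
  for (l in seq_len(spec$n_layers)) {
    if (skip[l]) next
    att <- mha_block_forward(p, paste0("enc", l), H, real_rows_list,
                             spec$n_heads, training, dropout)
    ffb <- ff_block_forward(p, paste0("enc", l), att$Y, training, dropout)
    layer_caches[[l]] <- list(att = att$cache, ff = ffb$cache)
    H <- ffb$Y
  }
  xattn_cache <- NULL
  if (spec$extra_attention) {
    xat <- mha_block_forward(p, "xattn", H, real_rows_list, spec$n_heads,
                             training, dropout)
    xattn_cache <- xat$cache
    H <- xat$Y
  }
  # dual-feature fusion: pooled [CLS] state + mask-weighted mean over real
  # tokens, concatenated
  P <- matrix(0, B, d); G <- matrix(0, B, d)
  for (b in seq_len(B)) {
    rows <- real_rows_list[[b]]
    P[b, ] <- H[rows[1L], ]
    G[b, ] <- colMeans(H[rows, , drop = FALSE])
  }
  C <- cbind(P, G)
  Z1 <- sweep(C %*% p$mlp_W1, 2L, p$mlp_b1, `+`)
  M1 <- pmax(Z1, 0)
  m1mask <- if (training && dropout > 0) {
    drop_mask(nrow(M1), ncol(M1), dropout)
  } else NULL
  M1d <- apply_drop(M1, m1mask)
  Z2 <- sweep(M1d %*% p$mlp_W2, 2L, p$mlp_b2, `+`)
  Fe <- pmax(Z2, 0)
  y_phq <- drop(Fe %*% p$head_phq_reg_W) + p$head_phq_reg_b
  y_gad <- drop(Fe %*% p$head_gad_reg_W) + p$head_gad_reg_b
  logit_phq <- sweep(Fe %*% p$head_phq_cls_W, 2L, p$head_phq_cls_b, `+`)
  logit_gad <- sweep(Fe %*% p$head_gad_cls_W, 2L, p$head_gad_cls_b, `+`)
  out <- list(
    y_phq_reg = y_phq, y_gad_reg = y_gad,
    logit_phq = logit_phq, logit_gad = logit_gad,
    p_phq_cls = softmax(logit_phq), p_gad_cls = softmax(logit_gad),
    f_enhanced = Fe, f_combined = C,
    hidden = lapply(seq_len(B), function(b) {
      H[real_rows_list[[b]], , drop = FALSE]
    })
  )
  if (keep_cache) {
    out$cache <- list(ids_list = ids_list, lens = lens, Lb = Lb,
                      real_rows_list = real_rows_list,
                      layer_caches = layer_caches, skip = skip,
                      xattn_cache = xattn_cache,
                      H_final = H, P = P, G = G, C = C,
                      M1 = M1, M1d = M1d, m1mask = m1mask, Fe = Fe, Z2 = Z2)
  }
  out
}

#' Backward pass over a batch
#'
#' Propagates gradients of a scalar loss from the four head outputs back to
#' every parameter. `d_out` carries `dy_phq_reg`, `dy_gad_reg` (length-B
#' vectors) and `dlogit_phq`, `dlogit_gad` (B x 3 matrices, gradients with
#' respect to the pre-softmax logits).
#'
#' @param model A `phqgad_model`.
#' @param fw Forward result from [model_forward()] with `keep_cache = TRUE`.
#' @param d_out List of output gradients.
#' @return Flat named list of parameter gradients (same shapes as params).
#' @export
model_backward <- function(model, fw, d_out) {
  spec <- model$spec
  p <- model$params
  cache <- fw$cache
  stopifnot(!is.null(cache))
  Fe <- cache$Fe
  B <- nrow(Fe)
  grads <- list()
  # heads
  dFe <- matrix(0, B, spec$mlp_out)
  for (task in c("phq", "gad")) {
    dy <- d_out[[paste0("dy_", task, "_reg")]]
    W <- p[[paste0("head_", task, "_reg_W")]]
    grads[[paste0("head_", task, "_reg_W")]] <- crossprod(Fe, matrix(dy))
    grads[[paste0("head_", task, "_reg_b")]] <- sum(dy)
    dFe <- dFe + matrix(dy) %*% t(W)
    dl <- d_out[[paste0("dlogit_", task)]]
    Wc <- p[[paste0("head_", task, "_cls_W")]]
    grads[[paste0("head_", task, "_cls_W")]] <- crossprod(Fe, dl)
    grads[[paste0("head_", task, "_cls_b")]] <- colSums(dl)
    dFe <- dFe + dl %*% t(Wc)
  }
  # fusion MLP (final ReLU, then two affine layers back to f_combined)
  dZ2 <- dFe * (cache$Z2 > 0)
  grads$mlp_W2 <- crossprod(cache$M1d, dZ2)
  grads$mlp_b2 <- colSums(dZ2)
  dM1 <- apply_drop(dZ2 %*% t(p$mlp_W2), cache$m1mask) * (cache$M1 > 0)
  grads$mlp_W1 <- crossprod(cache$C, dM1)
  grads$mlp_b1 <- colSums(dM1)
  dC <- dM1 %*% t(p$mlp_W1)
  d <- spec$hidden_dim
  dP <- dC[, seq_len(d), drop = FALSE]
  dG <- dC[, d + seq_len(d), drop = FALSE]
  dH <- matrix(0, nrow(cache$H_final), d)
  for (b in seq_len(B)) {
    rows <- cache$real_rows_list[[b]]
    dH[rows[1L], ] <- dH[rows[1L], ] + dP[b, ]
    dH[rows, ] <- dH[rows, ] +
      matrix(dG[b, ] / length(rows), length(rows), d, byrow = TRUE)
  }
  if (spec$extra_attention) {
    bk <- mha_block_backward(p, cache$xattn_cache, dH)
    grads <- c(grads, bk$grads)
    dH <- bk$dH
  }
  for (l in rev(seq_len(spec$n_layers))) {
    if (cache$skip[l]) next
    lc <- cache$layer_caches[[l]]
    bf <- ff_block_backward(p, lc$ff, dH)
    grads <- c(grads, bf$grads)
    ba <- mha_block_backward(p, lc$att, bf$dH)
    grads <- c(grads, ba$grads)
    dH <- ba$dH
  }
  # embeddings: scatter-add real rows back to token/position tables
  all_ids <- unlist(cache$ids_list)
  all_rows <- unlist(cache$real_rows_list)
  all_pos <- unlist(lapply(cache$lens, seq_len))
  dE <- dH[all_rows, , drop = FALSE]
  dtok <- rowsum(dE, group = all_ids)
  demb_tok <- matrix(0, spec$vocab_size, d)
  demb_tok[as.integer(rownames(dtok)), ] <- dtok
  dposm <- rowsum(dE, group = all_pos)
  demb_pos <- matrix(0, spec$max_len, d)
  demb_pos[as.integer(rownames(dposm)), ] <- dposm
  grads$emb_tok <- demb_tok
  grads$emb_pos <- demb_pos
  # zero grads for skipped layers so the flat list always has full support
  for (nm in setdiff(names(p), names(grads))) {
    g <- p[[nm]]
    grads[[nm]] <- if (is.matrix(g)) matrix(0, nrow(g), ncol(g)) else {
      rep(0, length(g))
    }
  }
  grads[names(p)]
}

#' Dual-feature fusion for a single sample
#'
#' Combines the pooled sentence-level state with the mask-weighted mean of
#' the token states: `f_combined = concat(f_pooled, f_global)`.
#'
#' @param H L x d hidden-state matrix.
#' @param mask Binary vector of length L (1 = real token).
#' @param pooled Length-d pooled vector (the [CLS] state for tiny encoders).
#' @return List with `f_pooled`, `f_global`, `f_combined` (length 2d).
#' @export
fuse <- function(H, mask, pooled) {
  stopifnot(length(mask) == nrow(H), length(pooled) == ncol(H))
  if (all(mask == 0)) stop("fuse: all-zero attention mask")
  w <- as.numeric(mask) / sum(mask)
  f_global <- drop(crossprod(H, w))
  list(f_pooled = pooled, f_global = f_global,
       f_combined = c(pooled, f_global))
}

#' Feature enhancement MLP for a single fused vector
#'
#' Two affine layers with ReLU activations:
#' `ReLU(W2 ReLU(W1 f_combined + b1) + b2)`.
#'
#' @param f_combined Length-2d fused feature vector.
#' @param params List with `W1` (2d x hidden), `b1`, `W2` (hidden x out),
#'   `b2`; defaults to widths 512 and 256.
#' @return Non-negative numeric vector (length `ncol(W2)`).
#' @export
enhance <- function(f_combined, params) {
  h <- pmax(drop(f_combined %*% params$W1) + params$b1, 0)
  pmax(drop(h %*% params$W2) + params$b2, 0)
}

#' Task-head predictions for a single enhanced vector
#'
#' @param f_enhanced Enhanced feature vector (length `mlp_out`).
#' @param heads List with `phq_reg_W`, `phq_reg_b`, `gad_reg_W`, `gad_reg_b`,
#'   `phq_cls_W`, `phq_cls_b`, `gad_cls_W`, `gad_cls_b`.
#' @param clamp Clamp regression outputs to the scale ranges (report-time
#'   convenience; never used inside the loss).
#' @return List with `y_phq_reg`, `y_gad_reg`, `y_phq_cls`, `y_gad_cls` (the
#'   class vectors are probability simplexes).
#' @export
predict_heads <- function(f_enhanced, heads, clamp = FALSE) {
  yp <- drop(f_enhanced %*% heads$phq_reg_W) + heads$phq_reg_b
  yg <- drop(f_enhanced %*% heads$gad_reg_W) + heads$gad_reg_b
  if (clamp) {
    yp <- min(max(yp, 0), .PHQ9_MAX)
    yg <- min(max(yg, 0), .GAD7_MAX)
  }
  list(
    y_phq_reg = yp, y_gad_reg = yg,
    y_phq_cls = drop(softmax(drop(f_enhanced %*% heads$phq_cls_W) +
                               heads$phq_cls_b)),
    y_gad_cls = drop(softmax(drop(f_enhanced %*% heads$gad_cls_W) +
                               heads$gad_cls_b))
  )
}

#' Predict on a corpus
#'
#' Tokenizes texts and runs the model in evaluation mode, in mini-batches.
#'
#' @param model A `phqgad_model`.
#' @param corpus Corpus data.frame.
#' @param tokenizer Tokenizer handle.
#' @param batch_size Mini-batch size for the forward pass.
#' @param clamp Clamp regression outputs to scale ranges.
#' @return Data.frame with `record_id`, regression predictions, predicted
#'   severity classes and class probabilities.
#' @export
model_predict <- function(model, corpus, tokenizer, batch_size = 64L,
                          clamp = TRUE) {
  ids_list <- lapply(corpus$text, function(tx) {
    tokenize(tx, tokenizer, model$spec$max_len)$token_ids
  })
  n <- length(ids_list)
  res <- vector("list", ceiling(n / batch_size))
  for (k in seq_along(res)) {
    sel <- ((k - 1L) * batch_size + 1L):min(k * batch_size, n)
    fw <- model_forward(model, ids_list[sel], training = FALSE)
    yp <- fw$y_phq_reg; yg <- fw$y_gad_reg
    if (clamp) {
      yp <- pmin(pmax(yp, 0), .PHQ9_MAX)
      yg <- pmin(pmax(yg, 0), .GAD7_MAX)
    }
    res[[k]] <- data.frame(
      record_id = corpus$record_id[sel],
      phq9_pred = yp, gad7_pred = yg,
      phq9_class = .SEVERITY_LEVELS[max.col(fw$p_phq_cls)],
      gad7_class = .SEVERITY_LEVELS[max.col(fw$p_gad_cls)],
      p_phq_mild = fw$p_phq_cls[, 1], p_phq_moderate = fw$p_phq_cls[, 2],
      p_phq_severe = fw$p_phq_cls[, 3],
      p_gad_mild = fw$p_gad_cls[, 1], p_gad_moderate = fw$p_gad_cls[, 2],
      p_gad_severe = fw$p_gad_cls[, 3],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
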