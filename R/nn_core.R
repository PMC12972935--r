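# Matrix neural-network primitives with hand-written backward passes.
# Everything operates on plain numeric matrices; parameters live in flat
# named lists so optimizers, EMA and serialization can treat them uniformly.

.LN_EPS <- 1e-5

#' Row-wise softmax
#'
#' @param x Numeric matrix (or vector, treated as one row).
#' @return Matrix of the same shape; rows are probability simplexes.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`: each output row is a convex combination of
#' the rows of `V`, with weights given by the softmax of scaled query-key
#' similarities.
#'
#' @param Q,K,V Conforming numeric matrices (`Q`: n_q x d_k, `K`: n_k x d_k,
#'   `V`: n_k x d_v).
#' @param d_k Key dimension used for scaling; defaults to `ncol(K)`.
#' @return List with `output` (n_q x d_v) and `weights` (n_q x n_k).
#' @export
attention <- function(Q, K, V, d_k = ncol(K)) {
  stopifnot(d_k > 0, ncol(Q) == ncol(K), nrow(K) == nrow(V))
  A <- softmax(Q %*% t(K) / sqrt(d_k))
  list(output = A %*% V, weights = A)
}

#' Multi-head self-attention on a hidden-state matrix
#'
#' Splits the hidden dimension into `h` heads, applies scaled dot-product
#' attention per head on learned projections, concatenates and projects back
#' (`Concat(head_1, ..., head_h) W_O`).
#'
#' @param H L x d hidden-state matrix.
#' @param h Number of heads; `d` must be divisible by `h`.
#' @param params List with d x d matrices `Wq`, `Wk`, `Wv`, `Wo`.
#' @return List with `output` (L x d) and per-head attention `weights`.
#' @export
multihead_attention <- function(H, h, params) {
  d <- ncol(H)
  if (d %% h != 0L) stop("hidden dim ", d, " not divisible by n_heads ", h)
  d_k <- d %/% h
  Q <- H %*% params$Wq
  K <- H %*% params$Wk
  V <- H %*% params$Wv
  O <- matrix(0, nrow(H), d)
  weights <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * d_k + 1L):(i * d_k)
    att <- attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                     V[, cols, drop = FALSE], d_k)
    O[, cols] <- att$output
    weights[[i]] <- att$weights
  }
  list(output = O %*% params$Wo, weights = weights)
}

# ---- layer norm ----------------------------------------------------------

layernorm_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + .LN_EPS)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, `*`)
  Y <- sweep(Y, 2L, b, `+`)
  list(Y = Y, xhat = xhat, inv = inv)
}

layernorm_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = dX,
       dg = colSums(dY * xhat),
       db = colSums(dY))
}

# ---- parameter initialization --------------------------------------------

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Encoder specification
#'
#' @param kind `"tiny_random"` (small randomly initialized encoder for
#'   desk-scale work) or `"pretrained"` (standard base dimensions — 12 layers,
#'   12 heads, d = 768 — with weights loadable from an archive; none are
#'   bundled).
#' @param n_layers,n_heads,hidden_dim Transformer dimensions; `hidden_dim`
#'   must be divisible by `n_heads`.
#' @param max_len Maximum sequence length the position table supports.
#' @param vocab_size Token vocabulary size (including reserved ids).
#' @param ff_dim Feed-forward inner width (default `2 * hidden_dim` for tiny
#'   encoders, `4 * hidden_dim` for base).
#' @param extra_attention Whether to include the additional self-attention
#'   block (with residual connection and layer norm) after the encoder.
#' @param mlp_hidden,mlp_out Fusion MLP widths (defaults 512 and 256).
#' @return A `phqgad_encoder_spec` list.
#' @export
encoder_spec <- function(kind = c("tiny_random", "pretrained"),
                         n_layers = NULL, n_heads = NULL, hidden_dim = NULL,
                         max_len = 96L, vocab_size = 200L, ff_dim = NULL,
                         extra_attention = TRUE,
                         mlp_hidden = 512L, mlp_out = 256L) {
  kind <- match.arg(kind)
  if (kind == "pretrained") {
    n_layers <- n_layers %||% 12L
    n_heads <- n_heads %||% 12L
    hidden_dim <- hidden_dim %||% 768L
    ff_dim <- ff_dim %||% (4L * hidden_dim)
  } else {
    n_layers <- n_layers %||% 2L
    n_heads <- n_heads %||% 2L
    hidden_dim <- hidden_dim %||% 32L
    ff_dim <- ff_dim %||% (2L * hidden_dim)
  }
  if (hidden_dim %% n_heads != 0L) {
    stop("hidden_dim must be divisible by n_heads")
  }
  structure(list(kind = kind, n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 hidden_dim = as.integer(hidden_dim),
                 max_len = as.integer(max_len),
                 vocab_size = as.integer(vocab_size),
                 ff_dim = as.integer(ff_dim),
                 extra_attention = isTRUE(extra_attention),
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_out = as.integer(mlp_out)),
            class = "phqgad_encoder_spec")
}

#' Initialize the multitask model
#'
#' Builds the full parameter set: token/position embeddings, transformer
#' encoder layers, the extra self-attention block, the fusion MLP
#' (2d -> mlp_hidden -> mlp_out with ReLU), and the four task heads (two
#' regression scalars, two 3-class softmax heads).
#'
#' @param spec An [encoder_spec()].
#' @param seed Integer seed for the initialization draw.
#' @return A `phqgad_model` list with `spec` and flat named `params`.
#' @export
init_multitask_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phqgad_encoder_spec"))
  d <- spec$hidden_dim
  with_seed(seed, {
    p <- list(
      emb_tok = matrix(stats::rnorm(spec$vocab_size * d, sd = 0.02),
                       spec$vocab_size, d),
      emb_pos = matrix(stats::rnorm(spec$max_len * d, sd = 0.02),
                       spec$max_len, d)
    )
    add_block <- function(p, prefix) {
      p[[paste0(prefix, "_Wq")]] <- glorot(d, d)
      p[[paste0(prefix, "_Wk")]] <- glorot(d, d)
      p[[paste0(prefix, "_Wv")]] <- glorot(d, d)
      p[[paste0(prefix, "_Wo")]] <- glorot(d, d)
      p[[paste0(prefix, "_ln1_g")]] <- rep(1, d)
      p[[paste0(prefix, "_ln1_b")]] <- rep(0, d)
      p
    }
    for (l in seq_len(spec$n_layers)) {
      pre <- paste0("enc", l)
      p <- add_block(p, pre)
      p[[paste0(pre, "_ff_W1")]] <- glorot(d, spec$ff_dim)
      p[[paste0(pre, "_ff_b1")]] <- rep(0, spec$ff_dim)
      p[[paste0(pre, "_ff_W2")]] <- glorot(spec$ff_dim, d)
      p[[paste0(pre, "_ff_b2")]] <- rep(0, d)
      p[[paste0(pre, "_ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "_ln2_b")]] <- rep(0, d)
    }
    if (spec$extra_attention) p <- add_block(p, "xattn")
    p$mlp_W1 <- glorot(2L * d, spec$mlp_hidden)
    p$mlp_b1 <- rep(0, spec$mlp_hidden)
    p$mlp_W2 <- glorot(spec$mlp_hidden, spec$mlp_out)
    p$mlp_b2 <- rep(0, spec$mlp_out)
    for (task in c("phq", "gad")) {
      p[[paste0("head_", task, "_reg_W")]] <- glorot(spec$mlp_out, 1L)
      p[[paste0("head_", task, "_reg_b")]] <- 0
      p[[paste0("head_", task, "_cls_W")]] <- glorot(spec$mlp_out, 3L)
      p[[paste0("head_", task, "_cls_b")]] <- rep(0, 3L)
    }
    structure(list(spec = spec, params = p), class = "phqgad_model")
  })
}

#' Partition model parameters into shared and task-specific sets
#'
#' The shared set holds the encoder, the extra attention block, embeddings
#' and the fusion MLP; the two head sets hold the depression (PHQ-9) and
#' anxiety (GAD-7) task heads. The three sets are disjoint and cover the full
#' parameter list.
#'
#' @param model A `phqgad_model`.
#' @return List of name vectors: `shared`, `depression_head`, `anxiety_head`.
#' @export
parameter_partition <- function(model) {
  nm <- names(model$params)
  dep <- grep("^head_phq_", nm, value = TRUE)
  anx <- grep("^head_gad_", nm, value = TRUE)
  list(shared = setdiff(nm, c(dep, anx)),
       depression_head = dep, anxiety_head = anx)
}
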