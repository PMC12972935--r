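# The network: attention oracles, fusion, MLP enhancement, heads, shape
# contracts, determinism, and gradient correctness.

test_that("attention matches a brute-force dense-math oracle", {
  withr::with_seed(1L, {
    Q <- matrix(rnorm(12), 3, 4)
    K <- matrix(rnorm(20), 5, 4)
    V <- matrix(rnorm(10), 5, 2)
  })
  got <- attention(Q, K, V, d_k = 4)
  # independent elementwise oracle
  S <- matrix(0, 3, 5)
  for (i in 1:3) for (j in 1:5) S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(4)
  A <- matrix(0, 3, 5)
  for (i in 1:3) A[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
  O <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) O[i, j] <- sum(A[i, ] * V[, j])
  expect_lt(max(abs(got$output - O)), 1e-6)
  expect_lt(max(abs(rowSums(got$weights) - 1)), 1e-6)
})

test_that("zero queries give uniform attention (column mean of V)", {
  withr::with_seed(2L, {
    K <- matrix(rnorm(20), 5, 4)
    V <- matrix(rnorm(15), 5, 3)
  })
  got <- attention(matrix(0, 2, 4), K, V)
  expect_lt(max(abs(got$output[1, ] - colMeans(V))), 1e-9)
})

test_that("a saturated aligned query recovers a single value row", {
  K <- diag(4) * 1  # orthogonal keys
  V <- matrix(rnorm(8), 4, 2)
  Q <- matrix(K[3, ] * 50, 1, 4)  # large scale saturates the softmax
  got <- attention(Q, K, V)
  expect_lt(max(abs(got$output - V[3, , drop = FALSE])), 1e-6)
})

test_that("multihead attention equals a brute-force two-head computation", {
  d <- 6L; h <- 2L; L <- 4L; d_k <- 3L
  withr::with_seed(3L, {
    H <- matrix(rnorm(L * d), L, d)
    params <- list(Wq = matrix(rnorm(36), d, d), Wk = matrix(rnorm(36), d, d),
                   Wv = matrix(rnorm(36), d, d), Wo = matrix(rnorm(36), d, d))
  })
  got <- multihead_attention(H, h, params)
  # oracle: explicit per-head computation then concat + project
  Q <- H %*% params$Wq; K <- H %*% params$Wk; V <- H %*% params$Wv
  heads <- lapply(1:h, function(i) {
    cols <- ((i - 1) * d_k + 1):(i * d_k)
    S <- Q[, cols] %*% t(K[, cols]) / sqrt(d_k)
    A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    A %*% V[, cols]
  })
  oracle <- do.call(cbind, heads) %*% params$Wo
  expect_lt(max(abs(got$output - oracle)), 1e-6)
  expect_equal(dim(got$output), dim(H))
})

test_that("single-head identity projections reduce to plain attention", {
  d <- 4L
  withr::with_seed(4L, H <- matrix(rnorm(12), 3, d))
  params <- list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d))
  got <- multihead_attention(H, 1L, params)
  ref <- attention(H, H, H, d)
  expect_lt(max(abs(got$output - ref$output)), 1e-12)
})

test_that("encoder obeys the shape contract and is deterministic in eval", {
  model <- tiny_model_fixture()
  ids <- c(2L, 5L, 9L, 3L, 7L)
  H1 <- encode(ids, model)
  expect_equal(dim(H1), c(5L, model$spec$hidden_dim))
  H2 <- encode(ids, model)
  expect_identical(H1, H2)
  expect_error(encode(rep(2L, 50L), model), "max_len")
})

test_that("encoder output is position-sensitive", {
  model <- tiny_model_fixture()
  a <- encode(c(2L, 5L, 9L, 3L), model)
  b <- encode(c(2L, 9L, 5L, 3L), model)  # swap two non-[CLS] tokens
  expect_gt(max(abs(a - b)), 1e-6)
})

test_that("fuse concatenates pooled and mask-weighted mean features", {
  v <- c(1, 2, 3, 4)
  H <- rbind(v, v, v)
  got <- fuse(H, mask = c(1, 1, 1), pooled = v)
  expect_equal(got$f_combined, c(v, v))
  expect_equal(length(got$f_combined), 8L)
  # mask excludes padding rows with nonzero states
  H2 <- rbind(v, v, c(9, 9, 9, 9))
  with_pad <- fuse(H2, mask = c(1, 1, 0), pooled = v)
  without <- fuse(H2, mask = c(1, 1, 1), pooled = v)
  expect_equal(with_pad$f_global, v)
  expect_false(isTRUE(all.equal(with_pad$f_global, without$f_global)))
  expect_error(fuse(H, mask = c(0, 0, 0), pooled = v), "all-zero")
})

test_that("enhance matches a hand-composed affine/ReLU oracle", {
  withr::with_seed(5L, {
    params <- list(W1 = matrix(rnorm(8 * 12), 8, 12), b1 = rnorm(12),
                   W2 = matrix(rnorm(12 * 6), 12, 6), b2 = rnorm(6))
    x <- rnorm(8)
  })
  got <- enhance(x, params)
  h <- pmax(as.numeric(t(params$W1) %*% x) + params$b1, 0)
  oracle <- pmax(as.numeric(t(params$W2) %*% h) + params$b2, 0)
  expect_lt(max(abs(got - oracle)), 1e-6)
  expect_true(all(got >= 0))
  zero <- enhance(x, list(W1 = matrix(0, 8, 12), b1 = rep(0, 12),
                          W2 = matrix(0, 12, 6), b2 = rep(0, 6)))
  expect_equal(zero, rep(0, 6))
})

test_that("predict_heads produces valid simplexes and closed-form softmax", {
  heads <- list(phq_reg_W = matrix(0, 4, 1), phq_reg_b = 0,
                gad_reg_W = matrix(0, 4, 1), gad_reg_b = 0,
                phq_cls_W = matrix(0, 4, 3), phq_cls_b = c(0, log(2), log(4)),
                gad_cls_W = matrix(0, 4, 3), gad_cls_b = rep(0, 3))
  got <- predict_heads(rep(1, 4), heads)
  expect_equal(got$y_phq_reg, 0)
  # logits (0, ln2, ln4) -> (1/7, 2/7, 4/7)
  expect_lt(max(abs(got$y_phq_cls - c(1, 2, 4) / 7)), 1e-9)
  expect_equal(got$y_gad_cls, rep(1 / 3, 3))
  withr::with_seed(6L, {
    heads$phq_cls_W <- matrix(rnorm(12), 4, 3)
    heads$gad_cls_W <- matrix(rnorm(12), 4, 3)
  })
  got2 <- predict_heads(rnorm(4), heads)
  expect_lt(abs(sum(got2$y_phq_cls) - 1), 1e-6)
  expect_true(all(got2$y_gad_cls >= 0))
})

test_that("end-to-end shape contract holds across specs", {
  for (cfgv in list(c(1L, 1L, 4L), c(2L, 2L, 8L), c(1L, 4L, 16L))) {
    spec <- encoder_spec("tiny_random", n_layers = cfgv[1], n_heads = cfgv[2],
                         hidden_dim = cfgv[3], max_len = 20L,
                         vocab_size = 30L, mlp_hidden = 10L, mlp_out = 6L)
    model <- init_multitask_model(spec, seed = 1L)
    fw <- model_forward(model, list(c(2L, 3L, 4L), c(2L, 9L)))
    expect_equal(length(fw$y_phq_reg), 2L)
    expect_equal(dim(fw$p_phq_cls), c(2L, 3L))
    expect_lt(max(abs(rowSums(fw$p_phq_cls) - 1)), 1e-6)
    expect_lt(max(abs(rowSums(fw$p_gad_cls) - 1)), 1e-6)
    expect_equal(ncol(fw$f_combined), 2L * cfgv[3])
    expect_equal(ncol(fw$f_enhanced), 6L)
    expect_true(all(fw$f_enhanced >= 0))
  }
})

test_that("parameter partition is disjoint and exhaustive", {
  model <- tiny_model_fixture()
  part <- parameter_partition(model)
  all_names <- sort(c(part$shared, part$depression_head, part$anxiety_head))
  expect_equal(all_names, sort(names(model$params)))
  expect_equal(length(intersect(part$depression_head, part$anxiety_head)), 0L)
  expect_true(all(grepl("^head_phq_", part$depression_head)))
})

test_that("analytic gradients match central finite differences", {
  model <- tiny_model_fixture()
  ids <- list(c(2L, 5L, 9L, 3L), c(2L, 7L, 4L, 11L, 6L), c(2L, 29L))
  yp <- c(3, 15, 8); yg <- c(2, 12, 6)
  w <- loss_weights(class_weights_phq = c(0.7, 1.1, 1.6),
                    class_weights_gad = c(0.9, 1.2, 1.4))
  lg <- multitask_loss_grad(model, ids, yp, yg, weights = w)
  f <- function(params) {
    m2 <- model; m2$params <- params
    multitask_loss_grad(m2, ids, yp, yg, weights = w)$total
  }
  eps <- 1e-6
  withr::with_seed(8L, {
    for (nm in c("enc1_Wq", "enc2_ff_W1", "xattn_Wo", "mlp_W1",
                 "head_phq_cls_W", "head_gad_reg_W", "emb_tok",
                 "enc1_ln1_g")) {
      p <- model$params[[nm]]
      for (i in sample(length(p), min(length(p), 4L))) {
        pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (f(pp) - f(pm)) / (2 * eps)
        ana <- lg$grads[[nm]][i]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
      }
    }
  })
})

test_that("gradients reach shared parameters from both tasks", {
  model <- tiny_model_fixture()
  ids <- list(c(2L, 5L, 9L), c(2L, 7L, 4L))
  yp <- c(3, 15); yg <- c(2, 12)
  norm2 <- function(g) sqrt(sum(unlist(g)^2))
  pick <- function(grads, nms) grads[nms]
  part <- parameter_partition(model)
  both <- multitask_loss_grad(model, ids, yp, yg,
                              weights = loss_weights())$grads
  expect_gt(norm2(pick(both, part$shared)), 0)
  expect_gt(norm2(pick(both, part$anxiety_head)), 0)
  # zeroing the anxiety task blocks its head gradients but not the shared
  # depression path
  dep_only <- multitask_loss_grad(model, ids, yp, yg,
                                  weights = loss_weights(lambda_A = 0,
                                                         gamma = 0))$grads
  expect_equal(norm2(pick(dep_only, part$anxiety_head)), 0)
  expect_gt(norm2(pick(dep_only, part$shared)), 0)
  expect_gt(norm2(pick(dep_only, part$depression_head)), 0)
})

test_that("beta = 0 silences classification-head gradients", {
  model <- tiny_model_fixture()
  ids <- list(c(2L, 5L, 9L), c(2L, 7L, 4L))
  g <- multitask_loss_grad(model, ids, c(3, 15), c(2, 12),
                           weights = loss_weights(beta = 0, gamma = 0))$grads
  expect_equal(max(abs(g$head_phq_cls_W)), 0)
  expect_equal(max(abs(g$head_gad_cls_W)), 0)
  expect_gt(max(abs(g$head_phq_reg_W)), 0)
})

test_that("forward pass is batch-invariant for padded batches", {
  # a short sample padded inside a longer batch gets the same output as
  # when forwarded alone
  model <- tiny_model_fixture()
  short <- c(2L, 5L, 9L)
  long <- c(2L, 7L, 4L, 11L, 6L, 8L, 13L)
  alone <- model_forward(model, list(short))
  batched <- model_forward(model, list(long, short))
  expect_lt(abs(alone$y_phq_reg[1] - batched$y_phq_reg[2]), 1e-10)
  expect_lt(max(abs(alone$p_gad_cls[1, ] - batched$p_gad_cls[2, ])), 1e-10)
})
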