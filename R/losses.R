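# The weighted multitask objective: MSE regression loss over both scales,
# class-weighted label-smoothed cross-entropy over both 3-class heads, and an
# explicit L2 penalty, combined as alpha * L_reg + beta * L_cls + gamma * L2.

#' Loss-weight bundle
#'
#' Holds every scalar of the multitask objective. Defaults follow the
#' shipped configuration: regression weight `alpha = 0.3`, classification
#' weight `beta = 6.0` (the asymmetry biases the shared representation
#' toward severity categorization), regularization weight `gamma = 0.01`
#' with L2 coefficient `lambda_l2 = 0.01`, per-task weights
#' `lambda_D = lambda_A = 1`, and label smoothing 0.1.
#'
#' @param alpha,beta,gamma Non-negative weights of the three loss terms.
#' @param lambda_l2 L2 coefficient inside the regularization term.
#' @param lambda_D,lambda_A Per-task (depression/anxiety) weights applied
#'   inside both the regression and classification terms. Setting
#'   `lambda_A = 0` reduces the objective to a pure depression model (the
#'   mechanism the ablation harness uses to remove multitask learning).
#' @param class_weights_phq,class_weights_gad Strictly positive length-3
#'   class weights; `NULL` means uniform until [compute_class_weights()]
#'   fills them from training labels.
#' @param label_smoothing Smoothing factor in `[0, 1)`.
#' @return A `phqgad_loss_weights` list.
#' @export
loss_weights <- function(alpha = 0.3, beta = 6.0, gamma = 0.01,
                         lambda_l2 = 0.01, lambda_D = 1, lambda_A = 1,
                         class_weights_phq = NULL, class_weights_gad = NULL,
                         label_smoothing = 0.1) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, lambda_l2 >= 0,
            lambda_D >= 0, lambda_A >= 0,
            label_smoothing >= 0, label_smoothing < 1)
  for (cw in list(class_weights_phq, class_weights_gad)) {
    if (!is.null(cw)) stopifnot(length(cw) == 3L, all(cw > 0))
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 lambda_l2 = lambda_l2, lambda_D = lambda_D,
                 lambda_A = lambda_A,
                 class_weights_phq = class_weights_phq %||% rep(1, 3L),
                 class_weights_gad = class_weights_gad %||% rep(1, 3L),
                 label_smoothing = label_smoothing),
            class = "phqgad_loss_weights")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (N_c * C)`: balanced classes give weight 1 everywhere, rare
#' classes are up-weighted. The identity `sum_c N_c * w_c = N` holds exactly.
#'
#' @param labels Severity labels (factor or character).
#' @param C Number of classes (default 3).
#' @return Numeric weight vector of length `C`, named by class.
#' @export
compute_class_weights <- function(labels, C = 3L) {
  labels <- factor(labels, levels = .SEVERITY_LEVELS[seq_len(C)])
  counts <- as.integer(table(labels))
  N <- length(labels)
  empty <- counts == 0L
  if (any(empty)) {
    warning("class(es) with zero samples: ",
            paste(levels(labels)[empty], collapse = ", "),
            "; weight computed against N_c = 1")
    counts[empty] <- 1L
  }
  stats::setNames(N / (counts * C), levels(labels))
}

#' Multitask regression loss
#'
#' Mean over samples of the per-task-weighted sum of squared errors on the
#' two scales.
#'
#' @param pred_phq,pred_gad Predicted continuous scores.
#' @param true_phq,true_gad True integer scores.
#' @param lambda_D,lambda_A Per-task weights (default 1).
#' @return Non-negative scalar; zero iff both predictions are exact.
#' @export
regression_loss <- function(pred_phq, pred_gad, true_phq, true_gad,
                            lambda_D = 1, lambda_A = 1) {
  n <- length(pred_phq)
  if (length(pred_gad) != n || length(true_phq) != n || length(true_gad) != n) {
    stop("regression_loss: length mismatch")
  }
  mean(lambda_D * (pred_phq - true_phq)^2 + lambda_A * (pred_gad - true_gad)^2)
}

# Smoothed one-hot target matrix: (1 - s) on the true class, s / C elsewhere
# added uniformly.
smooth_targets <- function(labels, s, C = 3L) {
  idx <- as.integer(factor(labels, levels = .SEVERITY_LEVELS))
  Y <- matrix(s / C, length(idx), C)
  Y[cbind(seq_along(idx), idx)] <- Y[cbind(seq_along(idx), idx)] + (1 - s)
  Y
}

#' Weighted, label-smoothed classification loss
#'
#' `-(1/N) sum_i sum_c w_c * y~_ic * log p_ic` summed over both tasks, where
#' `y~` is the smoothed one-hot target and `w_c` the class weight. Per-task
#' weights multiply each task's contribution.
#'
#' @param probs_phq,probs_gad N x 3 probability matrices.
#' @param labels_phq,labels_gad Severity labels.
#' @param weights A [loss_weights()] bundle (class weights, smoothing,
#'   per-task weights are read from it).
#' @return Non-negative scalar.
#' @export
classification_loss <- function(probs_phq, probs_gad, labels_phq, labels_gad,
                                weights = loss_weights()) {
  task_ce <- function(P, labels, w_c) {
    if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-6)) {
      stop("classification_loss: rows must be probability simplexes")
    }
    if (any(P < 1e-12)) {
      warning("probability clipped at 1e-12 to guard log(0)")
      P <- pmax(P, 1e-12)
    }
    Y <- smooth_targets(labels, weights$label_smoothing)
    W <- matrix(w_c, nrow(P), 3L, byrow = TRUE)
    -mean(rowSums(W * Y * log(P)))
  }
  weights$lambda_D * task_ce(probs_phq, labels_phq,
                             weights$class_weights_phq) +
    weights$lambda_A * task_ce(probs_gad, labels_gad,
                               weights$class_weights_gad)
}

#' L2 penalty over a parameter collection
#'
#' `lambda * sum over parameters of the squared entries`. By default the
#' training engine restricts the collection to head and fusion parameters so
#' the encoder is not penalized twice on top of optimizer weight decay.
#'
#' @param params Named list of numeric arrays (or a single array).
#' @param lambda_l2 Coefficient (default 0.01).
#' @return Non-negative scalar.
#' @export
l2_penalty <- function(params, lambda_l2 = 0.01) {
  if (!is.list(params)) params <- list(params)
  lambda_l2 * sum(vapply(params, function(x) sum(x^2), numeric(1)))
}

#' Combine loss components
#'
#' `alpha * reg + beta * cls + gamma * l2`.
#'
#' @param reg,cls,l2 Non-negative loss components.
#' @param w A [loss_weights()] bundle.
#' @return Scalar total loss.
#' @export
total_loss <- function(reg, cls, l2, w = loss_weights()) {
  stopifnot(reg >= 0, cls >= 0, l2 >= 0)
  w$alpha * reg + w$beta * cls + w$gamma * l2
}

# Names of the parameters the explicit L2 term covers by default.
l2_subset <- function(model) {
  grep("^(head_|mlp_)", names(model$params), value = TRUE)
}

#' Loss and gradients for one mini-batch
#'
#' Runs the forward pass, evaluates the full objective and backpropagates to
#' every parameter. This is the single place where loss arithmetic meets the
#' network; the training engine and the gradient-check tests both call it.
#'
#' @param model A `phqgad_model`.
#' @param ids_list List of token-id vectors.
#' @param true_phq,true_gad Integer score vectors (length B).
#' @param weights A [loss_weights()] bundle.
#' @param training Logical; enables dropout/stochastic depth.
#' @param dropout,depth_rate Regularization rates when `training`.
#' @param l2_params Names of parameters covered by the explicit L2 term;
#'   default heads + fusion MLP.
#' @return List with `total`, `reg`, `cls`, `l2`, per-task components, and
#'   `grads` (flat named list).
#' @export
multitask_loss_grad <- function(model, ids_list, true_phq, true_gad,
                                weights = loss_weights(), training = FALSE,
                                dropout = 0, depth_rate = 0,
                                l2_params = l2_subset(model)) {
  n <- length(ids_list)
  fw <- model_forward(model, ids_list, training = training, dropout = dropout,
                      depth_rate = depth_rate, keep_cache = TRUE)
  lab_phq <- severity_bin(true_phq)
  lab_gad <- severity_bin(true_gad)
  reg <- regression_loss(fw$y_phq_reg, fw$y_gad_reg, true_phq, true_gad,
                         weights$lambda_D, weights$lambda_A)
  cls <- classification_loss(fw$p_phq_cls, fw$p_gad_cls, lab_phq, lab_gad,
                             weights)
  l2 <- l2_penalty(model$params[l2_params], weights$lambda_l2)
  tot <- total_loss(reg, cls, l2, weights)
  # gradients w.r.t. head outputs
  d_out <- list(
    dy_phq_reg = weights$alpha * weights$lambda_D * 2 *
      (fw$y_phq_reg - true_phq) / n,
    dy_gad_reg = weights$alpha * weights$lambda_A * 2 *
      (fw$y_gad_reg - true_gad) / n
  )
  dlogit <- function(P, labels, w_c, lambda_task) {
    Y <- smooth_targets(labels, weights$label_smoothing)
    W <- matrix(w_c, nrow(P), 3L, byrow = TRUE)
    s_i <- rowSums(W * Y)
    weights$beta * lambda_task * (P * s_i - W * Y) / nrow(P)
  }
  d_out$dlogit_phq <- dlogit(fw$p_phq_cls, lab_phq,
                             weights$class_weights_phq, weights$lambda_D)
  d_out$dlogit_gad <- dlogit(fw$p_gad_cls, lab_gad,
                             weights$class_weights_gad, weights$lambda_A)
  grads <- model_backward(model, fw, d_out)
  coef <- 2 * weights$gamma * weights$lambda_l2
  if (coef > 0) {
    for (nm in l2_params) grads[[nm]] <- grads[[nm]] + coef * model$params[[nm]]
  }
  list(total = tot, reg = reg, cls = cls, l2 = l2,
       forward = fw, grads = grads)
}
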