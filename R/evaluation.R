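# Screening metrics: regression metrics, binary confusion-matrix metrics,
# rank-based AUC, severity-stratified multiclass metrics, and the
# component-toggle ablation harness.

#' Construct a 2x2 confusion matrix
#'
#' Orientation: rows = true (negative, positive), columns = predicted
#' (negative, positive), i.e. `[[TN, FP], [FN, TP]]`.
#'
#' @param tn,fp,fn,tp Non-negative integer cell counts.
#' @return A `phqgad_cm2` list.
#' @export
confusion_matrix2 <- function(tn, fp, fn, tp) {
  cells <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  stopifnot(all(cells >= 0), sum(cells) >= 1)
  structure(as.list(cells), class = "phqgad_cm2")
}

#' Binary classification metrics from a confusion matrix
#'
#' Standard definitions: accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`,
#' recall (sensitivity) `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' `f1_positive` the harmonic mean of precision and recall, and `f1_macro`
#' the mean of the two per-class F1 scores. Metrics with a zero denominator
#' are returned as `NA` with a `"undefined"` attribute naming them.
#'
#' @param cm A [confusion_matrix2()] (or a 2x2 matrix in the same
#'   orientation).
#' @return Named list of metrics.
#' @export
binary_metrics <- function(cm) {
  if (is.matrix(cm)) {
    cm <- confusion_matrix2(tn = cm[1, 1], fp = cm[1, 2],
                            fn = cm[2, 1], tp = cm[2, 2])
  }
  tn <- cm$tn; fp <- cm$fp; fn <- cm$fn; tp <- cm$tp
  total <- tn + fp + fn + tp
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  specificity <- safe(tn, tn + fp)
  npv <- safe(tn, tn + fn)
  f1_pos <- if (is.na(precision) || is.na(recall) ||
                (precision + recall) == 0) NA_real_ else {
    2 * precision * recall / (precision + recall)
  }
  f1_neg <- if (is.na(npv) || is.na(specificity) ||
                (npv + specificity) == 0) NA_real_ else {
    2 * npv * specificity / (npv + specificity)
  }
  out <- list(accuracy = (tp + tn) / total,
              precision = precision, recall = recall,
              sensitivity = recall, specificity = specificity,
              f1_positive = f1_pos,
              f1_macro = mean(c(f1_pos, f1_neg)))
  undef <- names(out)[vapply(out, is.na, logical(1))]
  if (length(undef) > 0L) attr(out, "undefined") <- undef
  out
}

#' Regression metrics
#'
#' MSE, RMSE (`sqrt(MSE)` exactly), MAE, Pearson correlation and
#' `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param preds,truths Equal-length numeric vectors (n >= 2).
#' @return Named list; `pearson_r` and `r2` are `NA` (flagged undefined)
#'   when the truths are constant.
#' @export
regression_metrics <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 2L)
  err <- preds - truths
  mse <- mean(err^2)
  out <- list(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)))
  if (stats::var(truths) == 0) {
    out$pearson_r <- NA_real_
    out$r2 <- NA_real_
    attr(out, "undefined") <- c("pearson_r", "r2")
  } else {
    out$pearson_r <- stats::cor(preds, truths)
    out$r2 <- 1 - sum(err^2) / sum((truths - mean(truths))^2)
  }
  out
}

#' Rank-based AUC
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half (equivalent to trapezoidal ROC integration and to the
#' Mann-Whitney statistic).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1).
#' @return AUC in `[0, 1]`; `NA` with an `undefined` attribute if only one
#'   class is present.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- "auc"
    return(out)
  }
  r <- rank(scores)  # midranks handle ties at 1/2
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Multiclass confusion matrix and per-stratum metrics
#'
#' 3x3 severity confusion counts (rows = true, columns = predicted) with
#' one-vs-rest accuracy, precision, recall, F1 and specificity per stratum.
#'
#' @param preds,truths Severity labels (factor or character).
#' @return List with `counts` (3x3), `per_stratum` (data.frame), and
#'   `overall_accuracy`.
#' @export
multiclass_confusion <- function(preds, truths) {
  stopifnot(length(preds) == length(truths))
  preds <- factor(preds, levels = .SEVERITY_LEVELS)
  truths <- factor(truths, levels = .SEVERITY_LEVELS)
  counts <- table(true = truths, predicted = preds)
  per <- do.call(rbind, lapply(.SEVERITY_LEVELS, function(lv) {
    tp <- sum(preds == lv & truths == lv)
    fp <- sum(preds == lv & truths != lv)
    fn <- sum(preds != lv & truths == lv)
    tn <- sum(preds != lv & truths != lv)
    m <- binary_metrics(confusion_matrix2(tn, fp, fn, tp))
    data.frame(stratum = lv, n = tp + fn, accuracy = (tp + tn) / length(preds),
               precision = m$precision, recall = m$recall,
               f1 = m$f1_positive, specificity = m$specificity)
  }))
  list(counts = counts, per_stratum = per,
       overall_accuracy = mean(as.character(preds) == as.character(truths)))
}

#' Full metrics report from predictions
#'
#' Computes, per task: regression metrics on the continuous head, AUC of the
#' continuous prediction against the thresholded (>= 10) true label, binary
#' screening metrics at the clinical cutoff, and severity-stratified
#' multiclass metrics from the classification head.
#'
#' @param preds Prediction data.frame from [model_predict()] or
#'   [ensemble_predict()].
#' @param truths Corpus data.frame aligned with `preds` (matched on
#'   `record_id` when both carry it).
#' @return A `phqgad_metrics_report` list with `phq9` and `gad7` components.
#' @export
metrics_report <- function(preds, truths) {
  if (all(c("record_id") %in% names(preds)) && "record_id" %in% names(truths)) {
    truths <- truths[match(preds$record_id, truths$record_id), ]
  }
  one_task <- function(pred_cont, pred_class, true_score) {
    pos <- true_score >= 10
    pred_pos <- pred_class == "severe"
    cm <- confusion_matrix2(tn = sum(!pred_pos & !pos),
                            fp = sum(pred_pos & !pos),
                            fn = sum(!pred_pos & pos),
                            tp = sum(pred_pos & pos))
    list(regression = regression_metrics(pred_cont, true_score),
         auc = as.numeric(auc(pred_cont, pos)),
         screening = binary_metrics(cm),
         screening_cm = cm,
         stratified = multiclass_confusion(pred_class,
                                           severity_bin(true_score)))
  }
  structure(list(
    phq9 = one_task(preds$phq9_pred, preds$phq9_class, truths$phq9),
    gad7 = one_task(preds$gad7_pred, preds$gad7_class, truths$gad7),
    n = nrow(preds)
  ), class = "phqgad_metrics_report")
}

#' Write a metrics report as JSON and CSV tables
#'
#' @param report A `phqgad_metrics_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    lapply(unclass(report), function(x) {
      if (is.list(x) && !is.null(x$stratified)) {
        x$stratified$counts <- as.data.frame(x$stratified$counts)
      }
      x
    }),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, pretty = TRUE,
    force = TRUE)
  reg <- do.call(rbind, lapply(c("phq9", "gad7"), function(task) {
    data.frame(task = task, as.data.frame(report[[task]]$regression),
               auc = report[[task]]$auc)
  }))
  utils::write.csv(reg, file.path(dir, "regression_metrics.csv"),
                   row.names = FALSE)
  scr <- do.call(rbind, lapply(c("phq9", "gad7"), function(task) {
    data.frame(task = task, as.data.frame(report[[task]]$screening))
  }))
  utils::write.csv(scr, file.path(dir, "screening_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$phq9$stratified$per_stratum,
                   file.path(dir, "phq9_stratified.csv"), row.names = FALSE)
  invisible(dir)
}

#' Component-toggle ablation harness
#'
#' Trains the full model and one variant per toggle under identical data and
#' seeds, and reports per-task screening-F1 and MSE deltas relative to the
#' full model, mean and sd over seeds. Supported toggles: `"multitask"`
#' (replaced by two single-task models sharing the budget), `"augmentation"`
#' (training split used unaugmented) and `"component:extra_attention"`
#' (extra self-attention block removed). The reference row is exactly zero
#' by construction.
#'
#' @param split A `phqgad_split`.
#' @param toggles Character vector of toggles (may be empty).
#' @param spec Encoder spec for all variants.
#' @param weights Loss weights.
#' @param config Train config; per-seed runs derive their seeds from
#'   `config$seed + seq_len(n_seeds) - 1`.
#' @param n_seeds Number of seeds.
#' @param augment_args When the base pipeline augments, a list of arguments
#'   for [augment_to_balance()] applied to the training split (`NULL` for no
#'   augmentation — then the `"augmentation"` toggle is a no-op).
#' @return Data.frame in ablation-table layout: one reference row plus one
#'   row per toggle with mean/sd deltas.
#' @export
run_ablation <- function(split, toggles = character(0), spec = NULL,
                         weights = loss_weights(), config = train_config(),
                         n_seeds = 3L, augment_args = NULL) {
  seeds <- config$seed + seq_len(n_seeds) - 1L
  eval_run <- function(variant, seed) {
    cfg <- config
    cfg$seed <- seed
    tr_split <- split
    if (!is.null(augment_args) && variant != "augmentation") {
      aug <- do.call(augment_to_balance, c(list(corpus = split$train),
                                           augment_args))
      tr_split$train <- aug$corpus
    }
    run_spec <- spec
    if (variant == "component:extra_attention" && !is.null(run_spec)) {
      run_spec$extra_attention <- FALSE
    }
    measure <- function(res) {
      preds <- model_predict(res$model, split$validation, res$tokenizer)
      rep <- metrics_report(preds, split$validation)
      c(f1_phq = rep$phq9$screening$f1_positive,
        f1_gad = rep$gad7$screening$f1_positive,
        mse_phq = rep$phq9$regression$mse,
        mse_gad = rep$gad7$regression$mse)
    }
    if (variant == "multitask") {
      w_dep <- weights; w_dep$lambda_A <- 0
      w_anx <- weights; w_anx$lambda_D <- 0
      res_d <- train_multitask(tr_split, weights = w_dep, config = cfg,
                               spec = run_spec, monitor_task = "phq")
      res_a <- train_multitask(tr_split, weights = w_anx, config = cfg,
                               spec = run_spec, monitor_task = "gad")
      md <- measure(res_d); ma <- measure(res_a)
      c(f1_phq = unname(md["f1_phq"]), f1_gad = unname(ma["f1_gad"]),
        mse_phq = unname(md["mse_phq"]), mse_gad = unname(ma["mse_gad"]))
    } else {
      measure(train_multitask(tr_split, weights = weights, config = cfg,
                              spec = run_spec))
    }
  }
  full <- t(vapply(seeds, function(s) eval_run("full", s), numeric(4)))
  rows <- list(data.frame(
    configuration = "full (reference)",
    d_f1_phq_mean = 0, d_f1_phq_sd = 0, d_f1_gad_mean = 0, d_f1_gad_sd = 0,
    d_mse_phq_mean = 0, d_mse_phq_sd = 0, d_mse_gad_mean = 0,
    d_mse_gad_sd = 0))
  for (tg in toggles) {
    var <- t(vapply(seeds, function(s) eval_run(tg, s), numeric(4)))
    dd <- var - full
    rows[[length(rows) + 1L]] <- data.frame(
      configuration = paste0("- ", tg),
      d_f1_phq_mean = mean(dd[, "f1_phq"]), d_f1_phq_sd = stats::sd(dd[, "f1_phq"]),
      d_f1_gad_mean = mean(dd[, "f1_gad"]), d_f1_gad_sd = stats::sd(dd[, "f1_gad"]),
      d_mse_phq_mean = mean(dd[, "mse_phq"]), d_mse_phq_sd = stats::sd(dd[, "mse_phq"]),
      d_mse_gad_mean = mean(dd[, "mse_gad"]), d_mse_gad_sd = stats::sd(dd[, "mse_gad"]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
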