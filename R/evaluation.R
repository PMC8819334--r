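# Diagnostic-model evaluation: confusion-matrix metrics (Sn, Sp, Ac,
# PPV, NPV, MCC), ROC curves with rank-based AUC, DeLong confidence
# intervals, and learning curves.

#' Confusion matrix from predictions
#'
#' @param predicted logical/0-1 predicted classes (TRUE = positive).
#' @param truth logical/0-1 true classes.
#' @return list with TP, FP, FN, TN.
#' @export
confusion_matrix <- function(predicted, truth) {
  p <- as.logical(predicted); t <- as.logical(truth)
  stopifnot(length(p) == length(t))
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t),
       TN = sum(!p & !t))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, predictive values and Matthews
#' correlation coefficient. Metrics with a zero denominator are reported
#' as NA — except MCC, which is 0 by convention with `mcc_degenerate`
#' flagged.
#'
#' @param cm list or vector with TP, FP, FN, TN.
#' @return list with sn, sp, ac, ppv, npv, mcc and `mcc_degenerate`.
#' @export
compute_metrics <- function(cm) {
  cm <- as.list(cm)
  tp <- cm$TP; fp <- cm$FP; fn <- cm$FN; tn <- cm$TN
  if (any(c(tp, fp, fn, tn) < 0)) stop("negative counts", call. = FALSE)
  total <- tp + fp + fn + tn
  if (total < 1) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
    sqrt((tn + fn))
  degenerate <- mcc_den == 0
  mcc <- if (degenerate) 0 else (tp * tn - fp * fn) / mcc_den
  list(sn = safe_div(tp, tp + fn), sp = safe_div(tn, tn + fp),
       ac = (tp + tn) / total,
       ppv = safe_div(tp, tp + fp), npv = safe_div(tn, tn + fn),
       mcc = mcc, mcc_degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' Thresholds at every distinct score; AUC is the rank-based
#' (Mann-Whitney) statistic with ties counted one half, which equals the
#' trapezoid area under the empirical curve.
#'
#' @param scores numeric predictor values; larger = more positive.
#' @param labels logical/0-1 true classes.
#' @return list with `points` (data.frame fpr, tpr ordered from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / n0, numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- unique(pts[order(pts$fpr, pts$tpr), , drop = FALSE])
  rownames(pts) <- NULL
  list(points = pts, auc = univariate_auc(scores, labels))
}

#' DeLong confidence interval for an AUC
#'
#' DeLong's placement-value variance estimate with a logit-scale 95%
#' (or `conf`) interval, clipped to [0, 1]. Degenerate variance (e.g.
#' perfect separation) returns the point interval with a flag.
#'
#' @param scores,labels as in [roc_curve()].
#' @param conf confidence level (default 0.95).
#' @return list with auc, lo, hi, se and `degenerate`.
#' @export
auc_ci <- function(scores, labels, conf = 0.95) {
  labels <- as.logical(labels)
  x <- scores[labels]; y <- scores[!labels]    # cases, controls
  m <- length(x); n <- length(y)
  if (m < 2L || n < 2L) stop("need >= 2 samples per class", call. = FALSE)
  auc <- univariate_auc(scores, labels)
  # placement values
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                numeric(1))
  v01 <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m,
                numeric(1))
  var_auc <- stats::var(v10) / m + stats::var(v01) / n
  if (!is.finite(var_auc) || var_auc <= 0 || auc %in% c(0, 1)) {
    return(list(auc = auc, lo = auc, hi = auc, se = 0, degenerate = TRUE))
  }
  se <- sqrt(var_auc)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se_logit <- se / (auc * (1 - auc))
  lo <- stats::plogis(stats::qlogis(auc) - z * se_logit)
  hi <- stats::plogis(stats::qlogis(auc) + z * se_logit)
  list(auc = auc, lo = max(0, lo), hi = min(1, hi), se = se,
       degenerate = FALSE)
}

#' Evaluate a fitted panel on a labeled dataset
#'
#' @param model a `panel_model`.
#' @param X feature matrix containing the model's features.
#' @param y true binary labels.
#' @param cutoff probability cutoff for classification (default 0.5).
#' @return list with `metrics` (from [compute_metrics()]), `auc`,
#'   `auc_ci`, `cm` and the predicted probabilities.
#' @export
evaluate_panel <- function(model, X, y, cutoff = 0.5) {
  yv <- to_binary(y)
  pr <- predict(model, X)
  cm <- confusion_matrix(pr >= cutoff, yv == 1)
  ci <- auc_ci(pr, yv == 1)
  list(metrics = compute_metrics(cm), auc = ci$auc,
       auc_ci = c(lo = ci$lo, hi = ci$hi), cm = cm, prob = pr)
}

#' Learning curve of a logistic panel
#'
#' For each training fraction, a stratified subsample is drawn; the model
#' is fit on the whole subsample (training accuracy) and assessed by
#' stratified `folds`-fold CV within the subsample (validation accuracy).
#'
#' @param X feature matrix (the candidate panel's features).
#' @param y binary labels.
#' @param fractions increasing sample fractions in (0, 1].
#' @param folds CV folds (default 5).
#' @param seed RNG seed.
#' @param lambda ridge penalty.
#' @return data.frame: fraction, n, train_accuracy, validation_accuracy.
#'   Fractions leaving fewer than `folds` samples in a class are skipped
#'   with a warning.
#' @export
learning_curve <- function(X, y, fractions = seq(0.2, 1, by = 0.1),
                           folds = 5L, seed = 1L, lambda = 1e-4) {
  X <- as.matrix(X)
  yv <- to_binary(y)
  stopifnot(all(fractions > 0), all(fractions <= 1))
  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    idx <- if (f == 1) seq_along(yv) else
      with_seed((as.numeric(seed) * 503 + i) %% 2147483587, {
        unlist(lapply(unique(yv), function(cl) {
          w <- which(yv == cl)
          sample(w, max(1L, round(f * length(w))))
        }), use.names = FALSE)
      })
    ys <- yv[idx]
    if (min(table(ys)) < folds) {
      warning("fraction ", f, " leaves fewer samples than folds; skipped")
      next
    }
    fit <- fit_logistic(X[idx, , drop = FALSE], ys, lambda = lambda)
    tr_acc <- mean((predict(fit, X[idx, , drop = FALSE]) >= 0.5) == (ys == 1))
    sub <- (as.numeric(seed) * 907 + i) %% 2147483587
    val_acc <- with_seed(sub,
      cv_accuracy(X[idx, , drop = FALSE], ys, colnames(X), folds,
                  repeats = 1L, seed = sub,
                  lambda = lambda))
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = f, n = length(idx), train_accuracy = tr_acc,
      validation_accuracy = val_acc)
  }
  do.call(rbind, rows)
}

#' Format a metric report row (Table-style)
#'
#' @param panel,dataset labels for the report row.
#' @param ev result of [evaluate_panel()].
#' @return one-row data.frame with percentages at 2 decimals and MCC at 3.
#' @export
metric_report_row <- function(panel, dataset, ev) {
  m <- ev$metrics
  pct <- function(x) round(100 * x, 2)
  data.frame(panel = panel, dataset = dataset,
             auc = round(ev$auc, 3),
             ci_lo = round(ev$auc_ci[["lo"]], 3),
             ci_hi = round(ev$auc_ci[["hi"]], 3),
             sn = pct(m$sn), sp = pct(m$sp), ac = pct(m$ac),
             ppv = pct(m$ppv), npv = pct(m$npv), mcc = round(m$mcc, 3),
             stringsAsFactors = FALSE)
}
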