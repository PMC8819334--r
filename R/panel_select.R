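# Panel construction: differential feature reservation (DFR), one best
# peptide per protein, stratified train/validation split, and recursive
# feature elimination with repeated cross-validated logistic regression.

#' Differential feature reservation (DFR)
#'
#' Retains features passing all three pre-filter criteria: fold change of
#' at least `fc_threshold` in either direction (>= fc or <= 1/fc),
#' p-value below `p_threshold`, and VIP above `vip_threshold`.
#'
#' @param stats data.frame from [feature_stats()] (needs fc, p, vip).
#' @param fc_threshold fold-change threshold (default 1.2, two-sided).
#' @param p_threshold p-value threshold (default 0.05).
#' @param vip_threshold VIP threshold (default 1.0).
#' @return character vector of retained feature ids.
#' @export
dfr_filter <- function(stats, fc_threshold = 1.2, p_threshold = 0.05,
                       vip_threshold = 1.0) {
  stopifnot(all(c("feature_id", "fc", "p", "vip") %in% names(stats)))
  if (any(is.na(stats$vip))) {
    stop("VIP missing for: ",
         paste(stats$feature_id[is.na(stats$vip)], collapse = ", "),
         call. = FALSE)
  }
  keep <- (stats$fc >= fc_threshold | stats$fc <= 1 / fc_threshold) &
    stats$p < p_threshold & stats$vip > vip_threshold
  stats$feature_id[keep]
}

#' One best peptide per protein
#'
#' For proteins quantified through several peptides, keeps the peptide
#' with the highest univariate AUC (ties: smaller p, then lexicographic
#' feature id), so each retained feature represents a single protein.
#'
#' @param stats data.frame with feature_id, protein, auc, p.
#' @return subset of `stats`, one row per protein.
#' @export
best_peptide_per_protein <- function(stats) {
  stopifnot(all(c("feature_id", "protein", "auc", "p") %in% names(stats)))
  ord <- order(stats$protein, -stats$auc, stats$p, stats$feature_id)
  s <- stats[ord, , drop = FALSE]
  out <- s[!duplicated(s$protein), , drop = FALSE]
  out <- out[order(match(out$feature_id, stats$feature_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified train/validation split
#'
#' Per class, `round(fraction * n)` samples go to training; the rest form
#' the validation set. Deterministic under `seed`.
#'
#' @param labels class label per sample.
#' @param fraction training fraction (default 0.75, the usual 3:1 split).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
stratified_split <- function(labels, fraction = 0.75, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  with_seed(seed, {
    train <- unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(fraction * length(idx)))
    }), use.names = FALSE)
    train <- sort(train)
    list(train = train, validation = setdiff(seq_along(labels), train))
  })
}

# Ridge-penalized logistic regression by iteratively reweighted least
# squares; the intercept is unpenalized. X is the design without
# intercept. Returns list(intercept, coef, converged, iterations).
#' @keywords internal
logistic_irls <- function(X, y, lambda = 1e-4, max_iter = 200L,
                          tol = 1e-9) {
  n <- nrow(X); p <- ncol(X)
  Z <- cbind(1, X)
  beta <- numeric(p + 1L)
  pen <- c(0, rep(lambda, p))
  # penalized log-likelihood (to maximize); eta clipped against overflow
  obj <- function(b) {
    eta <- pmin(pmax(drop(Z %*% b), -30), 30)
    sum(y * eta - log1p(exp(eta))) - sum(pen * b^2) / 2
  }
  cur <- obj(beta)
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(Z %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, y - mu)) - pen * beta
    H <- crossprod(Z * w, Z) + diag(pen, p + 1L)
    step <- solve(H, grad)
    # step-halving: accept only improving (or numerically flat) steps
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      new <- obj(cand)
      if (new >= cur - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    improve <- new - cur
    beta <- cand; cur <- new
    if (abs(improve) < tol * (abs(cur) + 1)) {
      return(list(intercept = beta[1L], coef = beta[-1L],
                  converged = TRUE, iterations = it))
    }
  }
  list(intercept = beta[1L], coef = beta[-1L], converged = FALSE,
       iterations = max_iter)
}

#' Fit a logistic-regression panel model
#'
#' Features are standardized with training-data parameters (kept in the
#' model and reapplied verbatim at prediction time); the fit is maximum
#' likelihood with an optional small L2 penalty guarding against complete
#' separation.
#'
#' @param X n x p numeric matrix of training features (columns named).
#' @param y binary labels (logical, 0/1, or 2-level factor; second level /
#'   TRUE / 1 is the positive class).
#' @param lambda ridge penalty on standardized coefficients (default
#'   1e-4, effectively MLE).
#' @param standardize standardize columns with train mean/SD (default
#'   TRUE).
#' @return object of class `panel_model`: features, coefficients (on the
#'   standardized scale), intercept, center, scale, convergence info.
#' @export
fit_logistic <- function(X, y, lambda = 1e-4, standardize = TRUE) {
  X <- as.matrix(X)
  yv <- to_binary(y)
  if (nrow(X) <= ncol(X)) {
    warning("n <= p: coefficients may be unstable")
  }
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    Xs <- scale(X, center = center, scale = scl)
  } else {
    center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    Xs <- X
  }
  fit <- logistic_irls(Xs, yv, lambda = lambda)
  if (!fit$converged) {
    stop("logistic fit did not converge after ", fit$iterations,
         " iterations", call. = FALSE)
  }
  structure(list(features = colnames(X),
                 coef = stats::setNames(fit$coef, colnames(X)),
                 intercept = fit$intercept,
                 center = stats::setNames(center, colnames(X)),
                 scale = stats::setNames(scl, colnames(X)),
                 lambda = lambda, iterations = fit$iterations),
            class = "panel_model")
}

#' @keywords internal
to_binary <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("y must have two classes", call. = FALSE)
    as.numeric(y == levels(y)[2L])
  } else {
    yv <- as.numeric(as.logical(y) | y == 1)
    if (length(unique(yv)) != 2L) stop("y must have two classes", call. = FALSE)
    yv
  }
}

#' Predicted class-1 probabilities from a panel model
#'
#' @param object a `panel_model`.
#' @param newdata matrix/data.frame containing the model's features.
#' @param ... unused.
#' @return numeric vector of probabilities.
#' @export
predict.panel_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    stop("features absent from newdata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  Xs <- sweep(sweep(newdata[, object$features, drop = FALSE], 2,
                    object$center, "-"), 2, object$scale, "/")
  stats::plogis(object$intercept + drop(Xs %*% object$coef))
}

# Stratified fold assignment: per class, shuffled then dealt cyclically.
#' @keywords internal
stratified_folds <- function(y, folds) {
  out <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

# Mean held-out accuracy of a logistic model on feature subset `cols`
# over `repeats` rounds of stratified `folds`-fold CV.
#' @keywords internal
cv_accuracy <- function(X, yv, cols, folds, repeats, seed, lambda) {
  acc <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_id <- with_seed((as.numeric(seed) * 1009 + r) %% 2147483587,
                         stratified_folds(yv, folds))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- fit_logistic(X[tr, cols, drop = FALSE], yv[tr], lambda = lambda)
      pr <- predict(m, X[!tr, cols, drop = FALSE])
      acc <- c(acc, mean((pr >= 0.5) == (yv[!tr] == 1)))
    }
  }
  mean(acc)
}

#' Recursive feature elimination with cross-validation
#'
#' Backward elimination on standardized logistic coefficients: at each
#' step the mean held-out accuracy of the current subset is recorded
#' (stratified `folds`-fold CV repeated `repeats` times, folds re-drawn
#' per repeat from the master seed), then the feature with the smallest
#' absolute standardized coefficient in a full-training fit is dropped
#' (ties: larger univariate p if supplied, then column order). The final
#' subset size maximizes mean CV accuracy (ties: smaller size) and the
#' returned model is refit on the full training set.
#'
#' @param X n x p training matrix (named columns, p >= 2).
#' @param y binary labels.
#' @param folds CV folds (default 10).
#' @param repeats CV repetitions (default 10).
#' @param seed master seed for fold shuffling.
#' @param lambda ridge penalty passed to [fit_logistic()].
#' @param p_values optional named univariate p-values for tie-breaking.
#' @return `panel_model` with additional elements `cv_trace` (data.frame:
#'   size, features, mean_accuracy) and `selected` feature ids.
#' @export
rfe_cv <- function(X, y, folds = 10L, repeats = 10L, seed = 1L,
                   lambda = 1e-4, p_values = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  stopifnot(ncol(X) >= 2L)
  yv <- to_binary(y)
  if (folds > min(table(yv))) {
    stop("folds exceeds the smaller class count", call. = FALSE)
  }
  current <- colnames(X)
  trace_size <- integer(0); trace_acc <- numeric(0); trace_feats <- list()
  best_sets <- list()
  step <- 0L
  while (length(current) >= 1L) {
    step <- step + 1L
    acc <- cv_accuracy(X, yv, current, folds, repeats,
                       (as.numeric(seed) * 31 + step) %% 2147483587, lambda)
    trace_size <- c(trace_size, length(current))
    trace_acc <- c(trace_acc, acc)
    trace_feats[[step]] <- current
    if (length(current) == 1L) break
    full <- fit_logistic(X[, current, drop = FALSE], yv, lambda = lambda)
    imp <- abs(full$coef)
    worst <- min(imp)
    cand <- names(imp)[imp <= worst + 1e-12]
    if (length(cand) > 1L && !is.null(p_values)) {
      pv <- p_values[cand]
      cand <- cand[order(-pv, match(cand, current))]
    }
    current <- setdiff(current, cand[1L])
  }
  best <- which(trace_acc == max(trace_acc))
  best <- best[which.min(trace_size[best])]          # ties: smaller size
  selected <- trace_feats[[best]]
  model <- fit_logistic(X[, selected, drop = FALSE], yv, lambda = lambda)
  model$selected <- selected
  model$cv_trace <- data.frame(
    size = trace_size,
    features = vapply(trace_feats, paste, character(1), collapse = ";"),
    mean_accuracy = trace_acc, stringsAsFactors = FALSE)
  model$seed <- seed
  model
}
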