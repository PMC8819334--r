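# Univariate differential statistics and OPLS-DA with VIP scores.
# The univariate layer (rank tests, fold change, BH adjustment, volcano
# classification, per-feature AUC) feeds the DFR pre-filter; OPLS-DA
# supplies the VIP criterion.

#' Mann-Whitney U test
#'
#' Two-sided test of stochastic equality. The exact null distribution is
#' used when the pooled size is at most `exact_limit` and there are no
#' ties; otherwise a normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric samples (each nonempty).
#' @param exact_limit pooled-size threshold for the exact distribution
#'   (default 12, keeping full enumeration tractable).
#' @return list with `U` (statistic for `x`, ties counted 1/2) and `p`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)
  if (N <= exact_limit && !has_ties) {
    # exact two-sided p from the null distribution of U
    lo <- stats::pwilcox(U, m, n)
    hi <- stats::pwilcox(U - 1, m, n, lower.tail = FALSE)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- m * n / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- m * n / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Welch two-sample t test
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return list with `t`, `df`, `p` and `degenerate` (TRUE when both
#'   groups have zero variance, in which case p = 1 by convention).
#' @export
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; output order matches input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values, clipped at 1.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Linear-scale fold change
#'
#' @param x case values, `y` control values (linear scale).
#' @param aggregate "mean" or "median".
#' @return list with `fc` (case/control) and `log2_fc`.
#' @export
fold_change <- function(x, y, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  f <- if (aggregate == "mean") mean else stats::median
  denom <- f(y, na.rm = TRUE)
  if (!is.finite(denom) || denom <= 0) {
    stop("control aggregate must be positive", call. = FALSE)
  }
  fc <- f(x, na.rm = TRUE) / denom
  list(fc = fc, log2_fc = log2(fc))
}

#' Volcano classification
#'
#' Classifies features as up/down/ns at a symmetric log2 fold-change
#' cutoff and a significance criterion (raw or BH-adjusted p).
#'
#' @param log2_fc vector of log2 fold changes.
#' @param p vector of p-values (raw).
#' @param log2_cutoff nonnegative log2 FC cutoff (0.585 = 1.5-fold serum
#'   convention; 1 = 2-fold tissue convention).
#' @param p_cutoff significance level (default 0.05).
#' @param adjust "BH" to apply Benjamini-Hochberg before thresholding,
#'   "none" for raw p.
#' @return character vector in {"up", "down", "ns"}.
#' @export
volcano_classify <- function(log2_fc, p, log2_cutoff = 0.585,
                             p_cutoff = 0.05, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(log2_cutoff >= 0, p_cutoff >= 0)
  pp <- if (adjust == "BH") benjamini_hochberg(p) else p
  sig <- pp < p_cutoff
  out <- rep("ns", length(log2_fc))
  out[sig & log2_fc >= log2_cutoff] <- "up"
  out[sig & log2_fc <= -log2_cutoff] <- "down"
  out
}

#' Per-feature (univariate) ROC AUC
#'
#' Rank-based AUC = U / (n1 * n0), ties counted one half. Orientation:
#' larger values indicate the positive class unless `flip = TRUE`.
#'
#' @param values numeric scores.
#' @param labels logical or 0/1 vector, TRUE/1 = positive class.
#' @param flip reverse the orientation.
#' @return AUC in [0, 1].
#' @export
univariate_auc <- function(values, labels, flip = FALSE) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(values)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (flip) 1 - auc else auc
}

#' OPLS-DA with VIP scores
#'
#' Orthogonal-signal-corrected PLS1 in the Trygg-Wold style: the
#' requested number of y-orthogonal components is iteratively removed
#' from the (autoscaled) data, then a single predictive component is
#' extracted. VIP for feature j is `sqrt(p * w_j^2 / sum(w^2))` from the
#' predictive weights, so the VIP^2 values average to 1.
#'
#' @param X n x p numeric matrix (autoscaled internally; constant columns
#'   are dropped with a warning).
#' @param y binary class labels (two levels).
#' @param n_orthogonal number of orthogonal components removed before the
#'   predictive component (default 1; 0 reduces to PLS1).
#' @return list with `vip` (named by retained columns), `weights`,
#'   `scores` (predictive), `scores_ortho`, `dropped` (constant columns).
#' @export
opls_da <- function(X, y, n_orthogonal = 1L) {
  X <- as.matrix(X)
  yl <- as.factor(y)
  if (nlevels(yl) != 2L) stop("y must have exactly two classes", call. = FALSE)
  if (nrow(X) < 4L) stop("need at least 4 samples", call. = FALSE)
  yv <- as.numeric(yl == levels(yl)[2L])
  yv <- yv - mean(yv)

  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  Xc <- scale(X)                                     # autoscale
  p <- ncol(Xc)

  t_orth <- NULL
  if (n_orthogonal > 0L) {
    for (k in seq_len(n_orthogonal)) {
      w <- drop(crossprod(Xc, yv)); w <- w / sqrt(sum(w^2))
      tt <- drop(Xc %*% w)
      pp <- drop(crossprod(Xc, tt)) / sum(tt^2)
      w_o <- pp - drop(crossprod(w, pp)) * w
      nw <- sqrt(sum(w_o^2))
      if (nw < 1e-12) break                          # nothing orthogonal left
      w_o <- w_o / nw
      t_o <- drop(Xc %*% w_o)
      p_o <- drop(crossprod(Xc, t_o)) / sum(t_o^2)
      Xc <- Xc - tcrossprod(t_o, p_o)
      t_orth <- cbind(t_orth, t_o)
    }
  }
  w <- drop(crossprod(Xc, yv)); w <- w / sqrt(sum(w^2))
  tt <- drop(Xc %*% w)
  vip <- sqrt(p * w^2 / sum(w^2))
  names(vip) <- colnames(X)
  list(vip = vip, weights = stats::setNames(w, colnames(X)),
       scores = tt, scores_ortho = t_orth, dropped = dropped)
}

#' Per-feature differential statistics table
#'
#' Computes, for every (light-channel) feature, the linear-scale fold
#' change, Mann-Whitney p, BH-adjusted p, OPLS-DA VIP and univariate AUC
#' for a case/control contrast, plus the volcano direction call.
#'
#' @param norm_log features x samples matrix of normalized log10 areas.
#' @param case_ids,control_ids sample-id (column) vectors for the two
#'   groups.
#' @param feature_protein optional named vector mapping feature_id to
#'   protein accession (carried into the output).
#' @param n_orthogonal orthogonal components for OPLS-DA.
#' @param log2_cutoff,p_cutoff,adjust volcano thresholds (see
#'   [volcano_classify()]).
#' @return data.frame: feature_id, protein, fc, log2_fc, p, adj_p, vip,
#'   auc, direction.
#' @export
feature_stats <- function(norm_log, case_ids, control_ids,
                          feature_protein = NULL, n_orthogonal = 1L,
                          log2_cutoff = 0.585, p_cutoff = 0.05,
                          adjust = "BH") {
  stopifnot(all(case_ids %in% colnames(norm_log)),
            all(control_ids %in% colnames(norm_log)))
  lin <- 10^norm_log
  ids <- rownames(norm_log)
  fc <- numeric(length(ids)); pv <- numeric(length(ids))
  auc <- numeric(length(ids))
  for (i in seq_along(ids)) {
    xc <- lin[i, case_ids]; xn <- lin[i, control_ids]
    f <- fold_change(xc[!is.na(xc)], xn[!is.na(xn)])
    fc[i] <- f$fc
    pv[i] <- mann_whitney_u(xc[!is.na(xc)], xn[!is.na(xn)])$p
    vals <- c(xc, xn)
    labs <- rep(c(TRUE, FALSE), c(length(xc), length(xn)))
    ok <- !is.na(vals)
    auc[i] <- univariate_auc(vals[ok], labs[ok])
  }
  Xall <- t(norm_log[, c(case_ids, control_ids), drop = FALSE])
  yall <- rep(c(1, 0), c(length(case_ids), length(control_ids)))
  vip <- opls_da(Xall, yall, n_orthogonal = n_orthogonal)$vip
  vip_full <- stats::setNames(rep(NA_real_, length(ids)), ids)
  vip_full[names(vip)] <- vip
  data.frame(
    feature_id = ids,
    protein = if (is.null(feature_protein)) NA_character_ else
      unname(feature_protein[ids]),
    fc = fc, log2_fc = log2(fc), p = pv,
    adj_p = benjamini_hochberg(pv), vip = unname(vip_full), auc = auc,
    direction = volcano_classify(log2(fc), pv, log2_cutoff = log2_cutoff,
                                 p_cutoff = p_cutoff, adjust = adjust),
    stringsAsFactors = FALSE)
}
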