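# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths.

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
enum_mw_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  mu <- m * length(y) / 2
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Step-up BH adjustment straight from the definition.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# AUC by O(n^2) pairwise comparison, ties one half.
pairwise_auc <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# Maximum number of simultaneously open intervals, checked at every edge.
sweep_max_concurrent <- function(start, end) {
  pts <- sort(unique(c(start, end)))
  max(vapply(pts, function(t) sum(start <= t & end > t), integer(1)),
      vapply(start, function(t) sum(start <= t & end > t), integer(1)))
}

# Random peptide sequences over the 20 standard residues.
random_peptides <- function(n, len_range = c(6, 20), seed = 1) {
  set.seed(seed)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aas, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# Small synthetic cohort configuration used across tests (two balanced
# groups mapped onto the UR/NC labels, planted IA effects).
small_cfg <- function(n_features = 20, n_per_group = 30, planted = 1:3,
                      d = 1.5, batch_sd = 0.3, n_batches = 3, seed = 1) {
  syn_config(n_proteins = n_features, n_features = n_features,
             group_sizes = c(NC = n_per_group, UR = n_per_group, R = 0),
             n_batches = n_batches,
             planted_ia_features = planted,
             planted_rupture_features = integer(0),
             effect_d = d, batch_sd = batch_sd, residual_sd = 0.2,
             qc_per_batch = 2, n_heavy_refs = 5, seed = seed)
}
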