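# Synthetic proteomes and PRM serum cohorts. The generator states the
# world the downstream analysis assumes: log10-additive group effects
# (multiplicative on peak areas), per-batch instrument offsets shared by
# all features in a run, pooled QC injections, and spiked heavy-isotope
# reference peptides whose abundance is independent of disease group.
# Ground truth is returned alongside so recovery tests can score the
# pipeline against what was planted.

#' Synthetic-cohort configuration
#'
#' Defaults emulate the quantification cohort the package targets: 113
#' quantified peptide features over 212 serum samples — 100 normal
#' controls (NC), 57 unruptured (UR) and 55 ruptured (R) aneurysm
#' patients — run in batches with pooled-QC injections and 18 spiked
#' stable-isotope-labeled (SIL) reference peptides.
#'
#' @param n_proteins number of synthetic proteins backing the features.
#' @param n_features number of quantified light-channel peptide features.
#' @param group_sizes named counts for NC, UR and R samples.
#' @param n_batches number of acquisition batches.
#' @param planted_ia_features indices (into features) shifted in both IA
#'   groups (R and UR) relative to NC.
#' @param planted_rupture_features indices shifted in R relative to UR
#'   (and NC).
#' @param effect_d standardized mean shift (units of `residual_sd`, log10
#'   scale) applied to planted features.
#' @param batch_sd SD of the per-batch log10 offset shared by all features.
#' @param residual_sd SD of the per-measurement log10 noise (0.2 is a
#'   typical ~50% CV for scheduled PRM on serum).
#' @param qc_per_batch pooled-QC injections per batch.
#' @param n_heavy_refs number of heavy-channel SIL reference peptides.
#' @param dropout optional MCAR missing-at-random fraction (default 0).
#' @param seed master seed; fixed seed gives bit-identical cohorts.
#' @return a `syn_config` list, validated.
#' @export
syn_config <- function(n_proteins = 100L,
                       n_features = 113L,
                       group_sizes = c(NC = 100L, UR = 57L, R = 55L),
                       n_batches = 6L,
                       planted_ia_features = 1:6,
                       planted_rupture_features = 7:14,
                       effect_d = 1.5,
                       batch_sd = 0.3,
                       residual_sd = 0.2,
                       qc_per_batch = 3L,
                       n_heavy_refs = 18L,
                       dropout = 0,
                       seed = 1L) {
  stopifnot(n_proteins >= 1L, n_features >= 1L,
            all(c("NC", "UR", "R") %in% names(group_sizes)),
            all(group_sizes >= 0L), n_batches >= 1L,
            is.finite(effect_d), batch_sd >= 0, qc_per_batch >= 0L,
            n_heavy_refs >= 0L, dropout >= 0, dropout < 1)
  if (!is.numeric(residual_sd) || residual_sd <= 0) {
    stop("residual_sd must be positive", call. = FALSE)
  }
  if (length(planted_ia_features) &&
      max(planted_ia_features) > n_features ||
      length(planted_rupture_features) &&
      max(planted_rupture_features) > n_features) {
    stop("planted feature indices exceed n_features", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 n_features = as.integer(n_features),
                 group_sizes = group_sizes,
                 n_batches = as.integer(n_batches),
                 planted_ia_features = as.integer(planted_ia_features),
                 planted_rupture_features = as.integer(planted_rupture_features),
                 effect_d = effect_d, batch_sd = batch_sd,
                 residual_sd = residual_sd,
                 qc_per_batch = as.integer(qc_per_batch),
                 n_heavy_refs = as.integer(n_heavy_refs),
                 dropout = dropout, seed = as.integer(seed)),
            class = "syn_config")
}

#' Generate a synthetic proteome
#'
#' Random protein sequences over the 20 standard residues with
#' approximately uniprot-like composition, each guaranteed to contain
#' internal K/R so that tryptic digestion is nontrivial.
#'
#' @param n_proteins number of sequences (>= 1).
#' @param seed RNG seed.
#' @param min_length,max_length sequence length range.
#' @return `Biostrings::AAStringSet` named `SYNP0001`, ...
#' @export
generate_proteome <- function(n_proteins, seed = 1L,
                              min_length = 80L, max_length = 400L) {
  if (n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  # rough average amino-acid frequencies in human proteins
  freq <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8, E = 7.1,
            G = 6.6, H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7,
            P = 6.3, S = 8.3, T = 5.3, V = 6.0, W = 1.2, Y = 2.7)
  with_seed(seed, {
    lens <- sample(min_length:max_length, n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(n) {
      s <- sample(names(freq), n, replace = TRUE, prob = freq)
      if (!any(s[-n] %in% c("K", "R"))) {          # force a cleavage site
        s[sample(n - 1L, 1L)] <- sample(c("K", "R"), 1L)
      }
      paste(s, collapse = "")
    }, character(1))
    Biostrings::AAStringSet(stats::setNames(seqs, sprintf("SYNP%04d", seq_len(n_proteins))))
  })
}

#' Simulate a fragment-ion spectral library
#'
#' Deterministic per-seed b/y fragment intensities for each peptide, as a
#' stand-in for an empirical spectral library in assay-design runs.
#'
#' @param sequences peptide sequences.
#' @param seed RNG seed.
#' @return named list of data.frames (series, ordinal, intensity).
#' @export
simulate_spectral_library <- function(sequences, seed = 1L) {
  with_seed(seed, {
    out <- lapply(sequences, function(s) {
      n <- nchar(s)
      ords <- seq_len(max(n - 1L, 1L))
      df <- rbind(data.frame(series = "y", ordinal = ords),
                  data.frame(series = "b", ordinal = ords))
      # y-ions dominate in HCD spectra of tryptic peptides
      df$intensity <- stats::rlnorm(nrow(df), meanlog = ifelse(df$series == "y", 5, 4),
                                    sdlog = 1)
      df
    })
    stats::setNames(out, sequences)
  })
}

#' Generate a synthetic PRM cohort
#'
#' Light-channel log10 area for feature j in sample i is
#' `mu_j + beta_j * g(i) + b_batch(i) + eps`, with
#' `eps ~ N(0, residual_sd^2)` and `beta_j = d * residual_sd` for planted
#' features in the case group of their contrast. Heavy-channel reference
#' peptides get group-independent areas `mu_H + b_batch + eps` (spiked
#' post-digestion, so they share the instrument/batch offset but carry no
#' biology). QC samples are pooled aliquots: their light-channel mean is
#' the average of the group means, with the same batch offset and residual
#' noise. Areas are returned on the linear scale (`10^x`).
#'
#' @param cfg a [syn_config()].
#' @param truth optional ground truth from a previous call; when supplied
#'   the same feature means, effects and reference levels are reused (for
#'   generating an external validation cohort from the same population)
#'   while batch offsets and noise are redrawn.
#' @param seed optional seed overriding `cfg$seed` (used with `truth` for
#'   external cohorts).
#' @return list with elements
#'   \describe{
#'     \item{areas}{matrix (features + references) x samples, linear scale}
#'     \item{features}{data.frame: feature_id, protein, channel}
#'     \item{samples}{data.frame: sample_id, group, batch, is_qc}
#'     \item{truth}{planted feature ids per contrast, true means, batch
#'       offsets}
#'   }
#' @export
generate_cohort <- function(cfg, truth = NULL, seed = NULL) {
  stopifnot(inherits(cfg, "syn_config"))
  seed <- if (is.null(seed)) sub_seed(cfg$seed, "cohort") else as.integer(seed)
  p <- cfg$n_features
  nh <- cfg$n_heavy_refs
  gs <- cfg$group_sizes

  with_seed(seed, {
    if (is.null(truth)) {
      mu <- stats::runif(p, 4.5, 7.5)                  # log10 peak areas
      mu_h <- stats::runif(nh, 5, 7)
      beta_ia <- numeric(p)
      beta_ia[cfg$planted_ia_features] <- cfg$effect_d * cfg$residual_sd
      beta_r <- numeric(p)
      beta_r[cfg$planted_rupture_features] <- cfg$effect_d * cfg$residual_sd
      protein <- sprintf("SYNP%04d", ((seq_len(p) - 1L) %% cfg$n_proteins) + 1L)
    } else {
      mu <- truth$mu; mu_h <- truth$mu_heavy
      beta_ia <- truth$beta_ia; beta_r <- truth$beta_rupture
      protein <- truth$protein
    }
    batch_off <- stats::rnorm(cfg$n_batches, 0, cfg$batch_sd)

    groups <- rep(c("NC", "UR", "R"), times = gs[c("NC", "UR", "R")])
    n_bio <- length(groups)
    n_qc <- cfg$n_batches * cfg$qc_per_batch
    n <- n_bio + n_qc
    # interleave samples over batches in run order, QCs appended per batch
    batch_bio <- rep(seq_len(cfg$n_batches), length.out = n_bio)
    batch_bio <- sample(batch_bio)                      # randomized run order
    batch <- c(batch_bio, rep(seq_len(cfg$n_batches), each = cfg$qc_per_batch))
    is_qc <- c(rep(FALSE, n_bio), rep(TRUE, n_qc))
    group <- c(groups, rep("QC", n_qc))
    sample_id <- sprintf("S%04d", seq_len(n))

    # expected log10 level per feature x sample; QC pool = mean of the
    # three group means (unweighted pooled aliquot)
    pooled <- mu + beta_ia * 2 / 3 + beta_r / 3
    expect_light <- matrix(0, p, n)
    for (i in seq_len(n)) {
      expect_light[, i] <- if (is_qc[i]) pooled else switch(group[i],
        NC = mu,
        UR = mu + beta_ia,
        R  = mu + beta_ia + beta_r)
    }
    log_light <- expect_light +
      matrix(batch_off[batch], p, n, byrow = TRUE) +
      matrix(stats::rnorm(p * n, 0, cfg$residual_sd), p, n)
    log_heavy <- matrix(mu_h, nh, n) +
      matrix(batch_off[batch], nh, n, byrow = TRUE) +
      matrix(stats::rnorm(nh * n, 0, cfg$residual_sd), nh, n)

    areas <- rbind(10^log_light, 10^log_heavy)
    feature_id <- c(sprintf("PEP%03d", seq_len(p)),
                    sprintf("SIL%02d", seq_len(nh)))
    dimnames(areas) <- list(feature_id, sample_id)
    if (cfg$dropout > 0) {
      drop <- matrix(stats::runif(length(areas)) < cfg$dropout,
                     nrow(areas), ncol(areas))
      areas[drop] <- NA_real_
    }

    features <- data.frame(
      feature_id = feature_id,
      protein = c(protein, sprintf("SILREF%02d", seq_len(nh))),
      channel = rep(c("light", "heavy"), c(p, nh)),
      stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = sample_id, group = group,
                          batch = batch, is_qc = is_qc,
                          stringsAsFactors = FALSE)
    truth_out <- list(
      mu = mu, mu_heavy = mu_h, beta_ia = beta_ia, beta_rupture = beta_r,
      protein = protein,
      planted_ia = feature_id[seq_len(p)][beta_ia != 0],
      planted_rupture = feature_id[seq_len(p)][beta_r != 0],
      batch_offsets = batch_off)
    structure(list(areas = areas, features = features, samples = samples,
                   truth = truth_out),
              class = "prm_cohort")
  })
}

#' Write a cohort to long-format CSV + metadata TSV + ground-truth JSON
#'
#' @param cohort result of [generate_cohort()].
#' @param area_path CSV path for the long peak-area table (feature_id,
#'   protein, sample_id, batch, label, area).
#' @param meta_path TSV path for sample metadata (sample_id, group, batch,
#'   is_qc); NULL to skip.
#' @param truth_path JSON path for ground truth; NULL to skip.
#' @return invisibly, the long-format data.frame written.
#' @export
write_cohort <- function(cohort, area_path, meta_path = NULL,
                         truth_path = NULL) {
  a <- cohort$areas
  long <- data.frame(
    feature_id = rep(rownames(a), times = ncol(a)),
    protein = rep(cohort$features$protein, times = ncol(a)),
    sample_id = rep(colnames(a), each = nrow(a)),
    batch = rep(cohort$samples$batch, each = nrow(a)),
    label = rep(cohort$features$channel, times = ncol(a)),
    area = as.vector(a),
    stringsAsFactors = FALSE)
  long <- long[!is.na(long$area), , drop = FALSE]
  utils::write.csv(long, area_path, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(cohort$samples, meta_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (!is.null(truth_path)) {
    jsonlite::write_json(cohort$truth, truth_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(long)
}
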