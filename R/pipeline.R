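# Orchestration: run the full chain — synthetic cohort (or supplied
# data), normalization, differential statistics, DFR, peptide
# deduplication, stratified split, RFE-CV logistic panel, evaluation on
# training / internal validation / external cohorts — from one config.
# All user-facing R functions remain the primary interface; this module
# wires them together reproducibly and writes an auditable run directory.

#' Pipeline configuration
#'
#' @param contrast "IA_vs_NC" (ruptured and unruptured pooled as cases
#'   against normal controls) or "R_vs_UR" (ruptured as cases).
#' @param syn [syn_config()] for the discovery cohort (cohort I scale by
#'   default).
#' @param external_group_sizes group sizes of the synthetic external
#'   cohort (cohort II scale by default); NULL disables external
#'   validation.
#' @param train_fraction training fraction of the discovery cohort.
#' @param fc_threshold,p_threshold,vip_threshold DFR criteria.
#' @param folds,repeats RFE-CV settings.
#' @param lambda ridge penalty for logistic fits.
#' @param strict_mode when TRUE, DFR/VIP/dedup statistics are computed on
#'   the training partition only (no filter information from validation
#'   samples); default FALSE computes them on the full discovery cohort,
#'   which mirrors the usual field practice but leaks filter information.
#' @param seed master seed; every stage derives a named sub-seed from it.
#' @return a `run_config` list.
#' @export
run_config <- function(contrast = c("IA_vs_NC", "R_vs_UR"),
                       syn = syn_config(),
                       external_group_sizes = c(NC = 20L, UR = 6L, R = 6L),
                       train_fraction = 0.75,
                       fc_threshold = 1.2, p_threshold = 0.05,
                       vip_threshold = 1.0,
                       folds = 10L, repeats = 10L, lambda = 1e-4,
                       strict_mode = FALSE, seed = 1L) {
  contrast <- match.arg(contrast)
  structure(list(contrast = contrast, syn = syn,
                 external_group_sizes = external_group_sizes,
                 train_fraction = train_fraction,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 vip_threshold = vip_threshold, folds = folds,
                 repeats = repeats, lambda = lambda,
                 strict_mode = strict_mode, seed = as.integer(seed)),
            class = "run_config")
}

# Case indicator for a contrast. IA_vs_NC pools R and UR as cases;
# R_vs_UR drops NC.
#' @keywords internal
contrast_labels <- function(groups, contrast) {
  if (contrast == "IA_vs_NC") {
    keep <- groups %in% c("NC", "UR", "R")
    list(keep = keep, y = as.integer(groups[keep] %in% c("UR", "R")))
  } else {
    keep <- groups %in% c("UR", "R")
    list(keep = keep, y = as.integer(groups[keep] == "R"))
  }
}

# Normalized light-channel matrix + sample table for one cohort.
#' @keywords internal
prepare_cohort <- function(cohort) {
  ref_ids <- cohort$features$feature_id[cohort$features$channel == "heavy"]
  logm <- log10_transform(cohort$areas)
  norm <- normalize_two_step(logm, ref_ids, cohort$samples)
  light <- cohort$features$feature_id[cohort$features$channel == "light"]
  list(norm = norm[light, , drop = FALSE],
       samples = cohort$samples,
       protein = stats::setNames(cohort$features$protein,
                                 cohort$features$feature_id))
}

#' Run the full panel-discovery pipeline
#'
#' Generates (or accepts) a discovery cohort, normalizes it, computes the
#' differential-statistics table for the configured contrast, applies the
#' DFR filter and best-peptide-per-protein deduplication, splits
#' training/internal-validation samples 3:1 (stratified), runs RFE-CV
#' logistic regression on the training set, and evaluates the final panel
#' on the training, internal-validation and (synthetic) external sets.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, all artifacts (config
#'   snapshot, stats table, panel JSON, Table-style metric report TSV,
#'   manifest with md5 checksums) are written there.
#' @param cohort optional pre-built discovery `prm_cohort` (bypasses the
#'   generator).
#' @param external optional pre-built external `prm_cohort`.
#' @return list: stats, dfr_ids, panel_features, model, report
#'   (data.frame), evaluations, split, cohort, external.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL,
                         external = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$syn,
                              seed = sub_seed(config$seed, "cohort"))
  }
  if (is.null(external) && !is.null(config$external_group_sizes)) {
    ext_cfg <- config$syn
    ext_cfg$group_sizes <- config$external_group_sizes
    external <- generate_cohort(ext_cfg, truth = cohort$truth,
                                seed = sub_seed(config$seed, "external"))
  }
  prep <- prepare_cohort(cohort)
  bio <- !prep$samples$is_qc
  lab <- contrast_labels(prep$samples$group[bio], config$contrast)
  cols <- which(bio)[lab$keep]
  norm <- prep$norm[, cols, drop = FALSE]
  y <- lab$y
  sample_ids <- prep$samples$sample_id[cols]

  split <- stratified_split(y, fraction = config$train_fraction,
                            seed = sub_seed(config$seed, "split"))
  stats_cols <- if (config$strict_mode) split$train else seq_along(y)
  stats <- feature_stats(norm[, stats_cols, drop = FALSE],
                         case_ids = sample_ids[stats_cols][y[stats_cols] == 1],
                         control_ids = sample_ids[stats_cols][y[stats_cols] == 0],
                         feature_protein = prep$protein)
  dfr_ids <- dfr_filter(stats, config$fc_threshold, config$p_threshold,
                        config$vip_threshold)
  if (length(dfr_ids) < 2L) {
    stop("DFR retained fewer than 2 features; nothing to select from",
         call. = FALSE)
  }
  dedup <- best_peptide_per_protein(stats[stats$feature_id %in% dfr_ids, ,
                                          drop = FALSE])
  candidates <- dedup$feature_id

  Xtr <- t(norm[candidates, split$train, drop = FALSE])
  ytr <- y[split$train]
  model <- rfe_cv(Xtr, ytr, folds = config$folds, repeats = config$repeats,
                  seed = sub_seed(config$seed, "rfe"),
                  lambda = config$lambda,
                  p_values = stats::setNames(dedup$p, dedup$feature_id))

  Xval <- t(norm[model$selected, split$validation, drop = FALSE])
  evals <- list(
    training = evaluate_panel(model, t(norm[model$selected, split$train,
                                            drop = FALSE]), ytr),
    internal = evaluate_panel(model, Xval, y[split$validation]))
  if (!is.null(external)) {
    eprep <- prepare_cohort(external)
    ebio <- !eprep$samples$is_qc
    elab <- contrast_labels(eprep$samples$group[ebio], config$contrast)
    ecols <- which(ebio)[elab$keep]
    evals$external <- validate_external(
      model, t(eprep$norm[, ecols, drop = FALSE]), elab$y)
  }
  panel_name <- paste0("P", length(model$selected))
  report <- do.call(rbind, lapply(names(evals), function(ds) {
    metric_report_row(panel_name, ds, evals[[ds]])
  }))

  result <- list(stats = stats, dfr_ids = dfr_ids,
                 panel_features = model$selected, model = model,
                 report = report, evaluations = evals, split = split,
                 cohort = cohort, external = external, config = config)
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

#' Evaluate a trained panel on an external cohort
#'
#' Applies the training-time scaling and coefficients unchanged; the
#' external labels are used only to score predictions.
#'
#' @param model a `panel_model`.
#' @param X external feature matrix (samples x features).
#' @param y external binary labels.
#' @param cutoff probability cutoff (default 0.5).
#' @return as [evaluate_panel()].
#' @export
validate_external <- function(model, X, y, cutoff = 0.5) {
  evaluate_panel(model, X, y, cutoff = cutoff)
}

# Serialize a pipeline run into an auditable directory: stats TSV, panel
# JSON, metric report TSV, manifest with md5 checksums.
#' @keywords internal
write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  paths <- c(
    config = file.path(out_dir, "config.json"),
    stats = file.path(out_dir, "feature_stats.tsv"),
    panel = file.path(out_dir, "panel_model.json"),
    report = file.path(out_dir, "metric_report.tsv"))
  cfg_plain <- unclass(cfg)
  cfg_plain$syn <- unclass(cfg_plain$syn)
  jsonlite::write_json(cfg_plain, paths["config"], auto_unbox = TRUE,
                       digits = NA)
  utils::write.table(result$stats, paths["stats"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  m <- result$model
  jsonlite::write_json(
    list(features = m$selected,
         coefficients = as.list(m$coef),
         intercept = m$intercept,
         center = as.list(m$center), scale = as.list(m$scale),
         cv_trace = m$cv_trace),
    paths["panel"], auto_unbox = TRUE, digits = NA)
  utils::write.table(result$report, paths["report"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- data.frame(artifact = names(paths),
                         path = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
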