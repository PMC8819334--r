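# Peak-area ingestion and normalization. Peak areas arrive as a
# Skyline-export-style long CSV; analysis happens on a features x samples
# matrix. The two-step normalization removes within-batch instrument
# drift (longitudinal, anchored on spiked reference peptides) and
# between-batch level differences (transverse, per-feature batch-median
# centering), both as shifts on the log10 scale (= scalings on the linear
# scale, the standard instrument-drift model).

#' Read a long-format peak-area table
#'
#' @param path CSV with columns feature_id, sample_id, batch, label, area
#'   (a `protein` column, if present, is carried along).
#' @param meta_path optional TSV with sample_id, group, batch, is_qc;
#'   every sample in the area table must join.
#' @return a `prm_cohort`-style list: `areas` (features x samples matrix,
#'   linear scale; absent combinations NA), `features`, `samples`.
#' @export
read_peak_table <- function(path, meta_path = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("feature_id", "sample_id", "batch", "label", "area")
  miss <- setdiff(req, names(long))
  if (length(miss)) {
    stop("peak table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(long$feature_id, long$sample_id, long$label)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicate (feature, sample, label) row at line ", i + 1L, ": ",
         key[i], call. = FALSE)
  }
  feats <- unique(long[, intersect(c("feature_id", "protein", "label"),
                                   names(long)), drop = FALSE])
  names(feats)[names(feats) == "label"] <- "channel"
  if (anyDuplicated(feats$feature_id)) {
    stop("feature_id observed with more than one protein/label", call. = FALSE)
  }
  samp <- unique(long[, c("sample_id", "batch")])
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    bad <- setdiff(samp$sample_id, meta$sample_id)
    if (length(bad)) {
      stop("samples absent from metadata: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    samp <- meta[match(samp$sample_id, meta$sample_id), , drop = FALSE]
  }
  areas <- matrix(NA_real_, nrow(feats), nrow(samp),
                  dimnames = list(feats$feature_id, samp$sample_id))
  areas[cbind(match(long$feature_id, feats$feature_id),
              match(long$sample_id, samp$sample_id))] <- long$area
  rownames(samp) <- NULL
  rownames(feats) <- NULL
  structure(list(areas = areas, features = feats, samples = samp),
            class = "prm_cohort")
}

#' Log10-transform a peak-area matrix
#'
#' Zero areas become missing values (never -Inf); negative areas are a
#' data error.
#'
#' @param areas numeric matrix of linear-scale areas.
#' @return matrix of log10 areas.
#' @export
log10_transform <- function(areas) {
  if (any(areas < 0, na.rm = TRUE)) {
    stop("negative peak area encountered", call. = FALSE)
  }
  areas[!is.na(areas) & areas == 0] <- NA_real_
  log10(areas)
}

#' Two-step normalization of log10 peak areas
#'
#' Step 1 (longitudinal, within batch): each sample is shifted by the
#' difference between its reference-peptide median and the reference
#' median over that batch's QC runs, correcting run-to-run instrument
#' drift. Batches without QC runs fall back to the batch-wide reference
#' median. Step 2 (transverse, between batches): each feature is centered
#' on its per-batch median and re-anchored at its grand median, so after
#' normalization every feature's per-batch medians agree across batches.
#'
#' @param log_areas features x samples matrix of log10 areas.
#' @param reference_ids feature ids (rows) of the spiked reference
#'   peptides used as Step-1 anchors; each must be observed in every
#'   sample.
#' @param samples data.frame with sample_id, batch and is_qc matching the
#'   matrix columns.
#' @param steps which corrections to apply (default both, in order);
#'   mainly useful for diagnosing each step separately.
#' @return normalized matrix, same dimensions.
#' @export
normalize_two_step <- function(log_areas, reference_ids, samples,
                               steps = c("longitudinal", "transverse")) {
  steps <- match.arg(steps, several.ok = TRUE)
  stopifnot(is.matrix(log_areas), nrow(samples) == ncol(log_areas),
            length(reference_ids) >= 1L)
  if (!all(reference_ids %in% rownames(log_areas))) {
    stop("reference features absent from matrix: ",
         paste(setdiff(reference_ids, rownames(log_areas)), collapse = ", "),
         call. = FALSE)
  }
  ref <- log_areas[reference_ids, , drop = FALSE]
  ref_med <- apply(ref, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(ref_med))) {
    stop("no reference feature observed in sample(s): ",
         paste(samples$sample_id[!is.finite(ref_med)], collapse = ", "),
         call. = FALSE)
  }
  batch <- samples$batch
  is_qc <- if (!is.null(samples$is_qc)) as.logical(samples$is_qc) else
    rep(FALSE, nrow(samples))

  out <- log_areas
  if ("longitudinal" %in% steps) {
    # Step 1: per-sample shift to the batch's QC anchor
    for (b in unique(batch)) {
      in_b <- batch == b
      anchor_cols <- in_b & is_qc
      if (!any(anchor_cols)) anchor_cols <- in_b   # fallback: batch-wide
      anchor <- stats::median(ref_med[anchor_cols])
      shift <- ref_med[in_b] - anchor
      out[, in_b] <- sweep(out[, in_b, drop = FALSE], 2, shift, "-")
    }
  }
  if ("transverse" %in% steps) {
    # Step 2: per-feature batch-median centering, re-anchored at the
    # grand median
    grand <- apply(out, 1, stats::median, na.rm = TRUE)
    for (b in unique(batch)) {
      in_b <- batch == b
      bmed <- apply(out[, in_b, drop = FALSE], 1, stats::median, na.rm = TRUE)
      out[, in_b] <- out[, in_b, drop = FALSE] - bmed + grand
    }
  }
  out
}

#' Flag sparsely observed features
#'
#' @param areas features x samples matrix (linear or log scale).
#' @param min_observed_fraction minimum fraction of samples in which a
#'   feature must be observed (default 0.5).
#' @return character vector of flagged feature ids.
#' @export
flag_sparse_features <- function(areas, min_observed_fraction = 0.5) {
  frac <- rowMeans(!is.na(areas))
  rownames(areas)[frac < min_observed_fraction]
}

#' Stable-isotope-dilution quantification
#'
#' Endogenous (light) concentration from the spiked heavy internal
#' standard: `C_endogenous = C_SIS * area_endogenous / area_SIS`, with the
#' light/heavy ratio reported on the log2 scale.
#'
#' @param area_endogenous,area_sis light and heavy channel peak areas
#'   (vectors recycle).
#' @param c_sis known spiked concentration of the heavy standard (any
#'   unit; `C_endogenous` is in the same unit).
#' @return data.frame with area_endogenous, area_sis, c_sis, c_endogenous
#'   and log2_ratio.
#' @export
quantify_sil <- function(area_endogenous, area_sis, c_sis) {
  if (any(area_sis <= 0, na.rm = TRUE)) {
    stop("area_sis must be positive", call. = FALSE)
  }
  if (any(c_sis <= 0, na.rm = TRUE)) {
    stop("c_sis must be positive", call. = FALSE)
  }
  ratio <- area_endogenous / area_sis
  data.frame(area_endogenous = area_endogenous, area_sis = area_sis,
             c_sis = c_sis, c_endogenous = c_sis * ratio,
             log2_ratio = log2(ratio))
}
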