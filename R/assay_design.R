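# Rule-based design of scheduled PRM assays: in-silico tryptic digestion,
# proteotypic-peptide filtering, precursor charge and transition selection.
# The detectability/retention-time predictor is pluggable; the shipped
# heuristic is a transparent, non-learned surrogate for an instrument model.

#' Tryptic in-silico digestion
#'
#' Cleaves C-terminal to K or R, suppressed when the following residue is
#' proline. With `missed > 0` all products spanning up to that many internal
#' cleavage sites are returned in addition to the fully cleaved set.
#'
#' @param sequence protein sequence (uppercase one-letter codes).
#' @param missed maximum number of missed cleavages (default 0).
#' @return character vector of peptides in N-to-C order (0-missed products
#'   first, then longer products ordered by start position).
#' @examples
#' digest("MAGICKEYSRPELLK")          # "MAGICK" "EYSRPELLK"
#' digest("AAAQQQ")                   # no cleavage site
#' @export
digest <- function(sequence, missed = 0L) {
  stopifnot(length(sequence) == 1L, missed >= 0L)
  chars <- check_residues(sequence)
  n <- length(chars)
  # cut points AFTER position i: K/R not followed by P
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts == n | chars[pmin(cuts + 1L, n)] != "P"]
  bounds <- unique(c(0L, cuts, n))          # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_seg <- length(starts)
  out <- character(0)
  for (m in 0:min(missed, n_seg - 1L)) {
    for (i in seq_len(n_seg - m)) {
      out <- c(out, substr(sequence, starts[i], ends[i + m]))
    }
  }
  out
}

#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass: sum of residue masses plus one water
#' (18.010565 Da). Additive over concatenation minus one water.
#'
#' @param sequence peptide sequence.
#' @return mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")  # 799.3600
#' @export
peptide_mass <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- check_residues(sequence)
  sum(AA_MONO_MASS[chars]) + MASS_WATER
}

#' Heuristic detectability and iRT predictor
#'
#' A deterministic, documented surrogate for a learned instrument-specific
#' model (which is out of scope here). Detectability is a logistic function
#' of peptide length and mean Kyte-Doolittle hydropathy (GRAVY); iRT is a
#' linear rescaling of GRAVY. Not trained on any data; intended for
#' synthetic pipelines and as the default plug-in where no real predictor
#' is available.
#'
#' @param sequences character vector of peptide sequences.
#' @return data.frame with columns `sequence`, `detectability` (in [0,1])
#'   and `irt` (dimensionless retention index).
#' @export
heuristic_predictor <- function(sequences) {
  gravy <- vapply(sequences, function(s) {
    chars <- check_residues(s)
    mean(KYTE_DOOLITTLE[chars])
  }, numeric(1), USE.NAMES = FALSE)
  len <- nchar(sequences)
  # peptides near tryptic-typical length (~12) and moderate hydrophobicity
  # score highest; coefficients chosen to spread scores across (0, 1)
  detect <- stats::plogis(0.3 * gravy + 0.1 * (20 - abs(len - 12)) - 0.5)
  data.frame(sequence = sequences,
             detectability = detect,
             irt = 50 + 25 * gravy,
             stringsAsFactors = FALSE)
}

# Fixed order in which rejection rules are applied; the first failing rule
# is the recorded reason.
PTP_REASONS <- c("not_unique", "length", "mass", "detectability",
                 "forbidden_residue", "no_valid_charge",
                 "too_few_transitions")

#' Proteotypic-peptide filtering
#'
#' Applies the standard targeted-assay eligibility rules to candidate
#' peptides: unique to one protein in the background proteome, 7-25
#' residues, monoisotopic mass at most 6000 Da, predicted detectability
#' above 0.5, and free of methionine/cysteine (plus any configured motif).
#' At most `max_per_protein` accepted peptides are kept per protein
#' (highest detectability); proteins left without any eligible peptide are
#' reported as uncovered.
#'
#' @param peptides data.frame with columns `protein` and `sequence`
#'   (e.g. the digest of each candidate protein).
#' @param predictor function mapping a character vector of sequences to a
#'   data.frame with `detectability` and `irt` (see [heuristic_predictor()]).
#' @param background character vector of all peptide sequences in the
#'   background proteome digest, used for the uniqueness rule. Defaults to
#'   the input peptides themselves.
#' @param min_length,max_length,max_mass,min_detectability rule thresholds.
#' @param forbidden_residues residues that disqualify a peptide (default M, C).
#' @param forbidden_motifs optional regular expressions; a match rejects the
#'   peptide with reason `forbidden_residue`.
#' @param max_per_protein accepted peptides retained per protein (default 2).
#' @return list with `accepted` (data.frame: protein, sequence, length,
#'   mass, detectability, irt), `rejected` (data.frame: protein, sequence,
#'   reason) and `uncovered` (accessions with no accepted peptide).
#' @export
filter_ptps <- function(peptides, predictor = heuristic_predictor,
                        background = NULL,
                        min_length = 7L, max_length = 25L,
                        max_mass = 6000, min_detectability = 0.5,
                        forbidden_residues = c("M", "C"),
                        forbidden_motifs = character(0),
                        max_per_protein = 2L) {
  stopifnot(is.data.frame(peptides),
            all(c("protein", "sequence") %in% names(peptides)))
  if (is.null(background)) {
    background <- peptides
  } else if (!is.data.frame(background)) {
    stop("background must be a data.frame with protein and sequence columns",
         call. = FALSE)
  }
  # uniqueness: number of distinct parent proteins in the background
  bg <- unique(background[, c("protein", "sequence")])
  n_parents <- table(bg$sequence)
  pred <- predictor(peptides$sequence)
  if (!is.data.frame(pred) || nrow(pred) != nrow(peptides) ||
      !all(c("detectability", "irt") %in% names(pred))) {
    stop("predictor must return detectability and irt for every peptide",
         call. = FALSE)
  }

  seqs <- peptides$sequence
  len <- nchar(seqs)
  mass <- vapply(seqs, peptide_mass, numeric(1), USE.NAMES = FALSE)
  has_forbidden <- grepl(paste0("[", paste(forbidden_residues, collapse = ""), "]"),
                         seqs)
  for (motif in forbidden_motifs) {
    has_forbidden <- has_forbidden | grepl(motif, seqs)
  }
  unique_flag <- as.integer(n_parents[seqs]) == 1L
  unique_flag[is.na(unique_flag)] <- TRUE   # not in background: trivially unique

  reason <- rep(NA_character_, nrow(peptides))
  reason[!unique_flag] <- "not_unique"
  fail_len <- is.na(reason) & (len < min_length | len > max_length)
  reason[fail_len] <- "length"
  fail_mass <- is.na(reason) & mass > max_mass
  reason[fail_mass] <- "mass"
  fail_det <- is.na(reason) & pred$detectability <= min_detectability
  reason[fail_det] <- "detectability"
  fail_res <- is.na(reason) & has_forbidden
  reason[fail_res] <- "forbidden_residue"

  acc <- data.frame(protein = peptides$protein, sequence = seqs,
                    length = len, mass = mass,
                    detectability = pred$detectability, irt = pred$irt,
                    stringsAsFactors = FALSE)[is.na(reason), , drop = FALSE]
  rej <- data.frame(protein = peptides$protein, sequence = seqs,
                    reason = reason,
                    stringsAsFactors = FALSE)[!is.na(reason), , drop = FALSE]

  # keep at most max_per_protein accepted peptides, highest detectability
  if (nrow(acc) > 0L) {
    ord <- order(acc$protein, -acc$detectability, acc$sequence)
    acc <- acc[ord, , drop = FALSE]
    keep <- unlist(lapply(split(seq_len(nrow(acc)), acc$protein),
                          function(i) i[seq_len(min(length(i), max_per_protein))]),
                   use.names = FALSE)
    acc <- acc[sort(keep), , drop = FALSE]
  }
  rownames(acc) <- NULL
  rownames(rej) <- NULL
  uncovered <- setdiff(unique(peptides$protein), unique(acc$protein))
  list(accepted = acc, rejected = rej, uncovered = uncovered)
}

#' Precursor charge-state selection
#'
#' Computes m/z for charges 1-3 and keeps those inside the instrument scan
#' range. When several charges are in range, 2+ is preferred, then 3+,
#' then 1+ (tryptic peptides predominantly ionize at 2+; the priority is a
#' reproducible surrogate for manual signal inspection).
#'
#' @param mass neutral monoisotopic mass in Da.
#' @param mz_range acceptable precursor m/z window (default c(350, 1250)).
#' @return list with `charge` and `mz`, or `NULL` when no charge yields an
#'   in-range m/z (reason `no_valid_charge`).
#' @export
select_precursor <- function(mass, mz_range = c(350, 1250)) {
  stopifnot(is.finite(mass), mass > 0)
  for (z in c(2L, 3L, 1L)) {
    mz <- (mass + z * MASS_PROTON) / z
    if (mz >= mz_range[1] && mz <= mz_range[2]) {
      return(list(charge = z, mz = mz))
    }
  }
  NULL
}

#' Transition selection from a spectral-library entry
#'
#' Short fragments (b1-b3, y1-y3) carry little specificity and are
#' excluded; the remaining fragments are ranked by library intensity
#' (ties broken by higher ordinal, then y before b) and the top `k` kept.
#'
#' @param library_entry data.frame with columns `series` ("b"/"y"),
#'   `ordinal`, `intensity` and optionally `mz`.
#' @param k number of transitions to monitor (default 3; at least 3
#'   eligible fragments are required).
#' @param min_ordinal smallest fragment ordinal retained (default 4).
#' @return data.frame of selected transitions with a `rank` column, or
#'   `NULL` when fewer than 3 eligible fragments exist
#'   (reason `too_few_transitions`).
#' @export
select_transitions <- function(library_entry, k = 3L, min_ordinal = 4L) {
  if (!is.data.frame(library_entry) || nrow(library_entry) == 0L) {
    stop("empty spectral-library entry", call. = FALSE)
  }
  stopifnot(all(c("series", "ordinal", "intensity") %in% names(library_entry)))
  elig <- library_entry[library_entry$ordinal >= min_ordinal, , drop = FALSE]
  if (nrow(elig) < 3L) return(NULL)
  ord <- order(-elig$intensity, -elig$ordinal,
               match(elig$series, c("y", "b")))
  sel <- elig[ord[seq_len(min(k, nrow(elig)))], , drop = FALSE]
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Scheduled-injection method table
#'
#' Centers a fixed-width elution window on each predicted retention time,
#' clipped to the gradient, and reports the maximum number of concurrently
#' monitored precursors.
#'
#' @param rt numeric vector of predicted retention times (minutes),
#'   named by assay/peptide id.
#' @param width window width in minutes (default 3, the usual scheduled-PRM
#'   setting).
#' @param gradient c(start, end) of the LC gradient in minutes.
#' @return data.frame (assay, rt, start, end) sorted by window start, with
#'   attribute `max_concurrent`.
#' @export
build_schedule <- function(rt, width = 3.0, gradient = c(0, 65)) {
  if (any(!is.finite(rt))) {
    stop("missing retention-time prediction for assays: ",
         paste(which(!is.finite(rt)), collapse = ", "), call. = FALSE)
  }
  ids <- if (is.null(names(rt))) as.character(seq_along(rt)) else names(rt)
  start <- pmax(gradient[1], rt - width / 2)
  end <- pmin(gradient[2], rt + width / 2)
  sched <- data.frame(assay = ids, rt = rt, start = start, end = end,
                      stringsAsFactors = FALSE)
  sched <- sched[order(sched$start, sched$end), , drop = FALSE]
  rownames(sched) <- NULL
  # sweep over window edges; half-open windows [start, end): an end and a
  # start at the same instant do not overlap
  ev <- rbind(data.frame(t = sched$start, d = 1), data.frame(t = sched$end, d = -1))
  ev <- ev[order(ev$t, ev$d), , drop = FALSE]
  attr(sched, "max_concurrent") <- if (nrow(ev)) max(cumsum(ev$d)) else 0L
  sched
}

#' End-to-end assay design for a set of candidate proteins
#'
#' Digests each protein, filters proteotypic peptides, selects precursor
#' charge and transitions, and builds the scheduled method table. The
#' retention time used for scheduling maps iRT linearly onto the gradient.
#'
#' @param proteins named character vector (or `Biostrings::AAStringSet`) of
#'   protein sequences, names are accessions.
#' @param spectral_library named list of library entries (per peptide
#'   sequence) as accepted by [select_transitions()]; missing entries
#'   reject the peptide with reason `too_few_transitions`.
#' @param predictor detectability/iRT predictor (default the heuristic).
#' @param missed maximum missed cleavages for the digest (default 0: the
#'   cleanest proteotypic definition).
#' @param k transitions per assay.
#' @param window_width scheduling window width (minutes).
#' @param gradient LC gradient span (minutes).
#' @param ... further arguments passed to [filter_ptps()].
#' @return list with `assays` (one row per accepted assay: protein,
#'   sequence, charge, precursor_mz, rt, window start/end, transitions as a
#'   list-column), `rejected` (audit trail) and `uncovered` proteins.
#' @export
design_assays <- function(proteins, spectral_library,
                          predictor = heuristic_predictor, missed = 0L,
                          k = 3L, window_width = 3.0, gradient = c(0, 65),
                          ...) {
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  stopifnot(!is.null(names(proteins)))
  pep <- do.call(rbind, lapply(names(proteins), function(acc) {
    data.frame(protein = acc, sequence = digest(proteins[[acc]], missed),
               stringsAsFactors = FALSE)
  }))
  pep <- unique(pep)
  flt <- filter_ptps(pep, predictor = predictor, background = pep, ...)
  acc <- flt$accepted
  rej <- flt$rejected

  rows <- vector("list", nrow(acc))
  trans <- vector("list", nrow(acc))
  keep <- logical(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    prec <- select_precursor(acc$mass[i])
    if (is.null(prec)) {
      rej <- rbind(rej, data.frame(protein = acc$protein[i],
                                   sequence = acc$sequence[i],
                                   reason = "no_valid_charge"))
      next
    }
    entry <- spectral_library[[acc$sequence[i]]]
    tr <- if (is.null(entry)) NULL else select_transitions(entry, k = k)
    if (is.null(tr)) {
      rej <- rbind(rej, data.frame(protein = acc$protein[i],
                                   sequence = acc$sequence[i],
                                   reason = "too_few_transitions"))
      next
    }
    keep[i] <- TRUE
    rows[[i]] <- data.frame(protein = acc$protein[i],
                            sequence = acc$sequence[i],
                            length = acc$length[i], mass = acc$mass[i],
                            detectability = acc$detectability[i],
                            irt = acc$irt[i],
                            charge = prec$charge, precursor_mz = prec$mz,
                            stringsAsFactors = FALSE)
    trans[[i]] <- tr
  }
  assays <- do.call(rbind, rows[keep])
  if (is.null(assays)) {
    return(list(assays = NULL, rejected = rej, uncovered = flt$uncovered))
  }
  # map iRT linearly onto the gradient for scheduling
  irt_span <- range(assays$irt)
  denom <- max(irt_span[2] - irt_span[1], 1e-9)
  assays$rt <- gradient[1] +
    (assays$irt - irt_span[1]) / denom * (gradient[2] - gradient[1])
  sched <- build_schedule(stats::setNames(assays$rt, assays$sequence),
                          width = window_width, gradient = gradient)
  assays$window_start <- sched$start[match(assays$sequence, sched$assay)]
  assays$window_end <- sched$end[match(assays$sequence, sched$assay)]
  assays$transitions <- trans[keep]
  rownames(assays) <- NULL
  list(assays = assays, rejected = rej, uncovered = flt$uncovered,
       max_concurrent = attr(sched, "max_concurrent"))
}

#' Write an isolation-list CSV and rejection audit TSV
#'
#' @param design result of [design_assays()].
#' @param isolation_path,audit_path output file paths (NULL to skip).
#' @return invisibly, the isolation-list data.frame.
#' @export
write_assay_design <- function(design, isolation_path = NULL,
                               audit_path = NULL) {
  a <- design$assays
  iso <- data.frame(sequence = a$sequence, protein = a$protein,
                    charge = a$charge,
                    precursor_mz = round(a$precursor_mz, 4),
                    window_start = round(a$window_start, 2),
                    window_end = round(a$window_end, 2),
                    transitions = vapply(a$transitions, function(tr) {
                      paste0(tr$series, tr$ordinal, collapse = ";")
                    }, character(1)),
                    stringsAsFactors = FALSE)
  if (!is.null(isolation_path)) {
    utils::write.csv(iso, isolation_path, row.names = FALSE)
  }
  if (!is.null(audit_path)) {
    utils::write.table(design$rejected, audit_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(iso)
}
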