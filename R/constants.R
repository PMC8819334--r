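# Physical constants and residue tables used throughout assay design.
# Monoisotopic masses; values fixed here so every module shares one table.

#' @keywords internal
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @keywords internal
MASS_WATER <- 18.010565

#' @keywords internal
MASS_PROTON <- 1.007276

# Kyte-Doolittle hydropathy index, used by the heuristic peptide predictor.
#' @keywords internal
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

#' @keywords internal
STANDARD_AA <- names(AA_MONO_MASS)

# Validate that a sequence uses only the 20 standard residues.
# Returns invisibly; raises a format error naming the first offender.
#' @keywords internal
check_residues <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- chars[!chars %in% STANDARD_AA]
  if (length(bad) > 0L) {
    stop("non-standard residue '", bad[1L], "' in sequence '", sequence, "'",
         call. = FALSE)
  }
  invisible(chars)
}
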