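# Internal helpers.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomness in the package flows through this helper so a
# master seed yields bit-identical output.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: named sub-streams from one master
# seed, kept below 2^31.
#' @keywords internal
sub_seed <- function(seed, stream) {
  offsets <- c(proteome = 11L, cohort = 23L, library = 37L, split = 53L,
               rfe = 67L, curve = 79L, external = 97L, qc = 113L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 127 + off) %% 2147483587)
}
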