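test_that("long peak tables pivot and validate", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  long <- data.frame(feature_id = rep(c("f1", "f2", "f3"), 2),
                     sample_id = rep(c("s1", "s2"), each = 3),
                     batch = 1, label = "light",
                     area = c(10, 20, 30, 40, 50, 60))
  write.csv(long, tmp, row.names = FALSE)
  pam <- read_peak_table(tmp)
  expect_equal(dim(pam$areas), c(3, 2))
  expect_equal(pam$areas["f2", "s2"], 50)

  write.csv(rbind(long, long[1, ]), tmp, row.names = FALSE)
  expect_error(read_peak_table(tmp), "duplicate")

  write.csv(long[, -5], tmp, row.names = FALSE)
  expect_error(read_peak_table(tmp), "missing column")
})

test_that("log10 transform maps zeros to NA and rejects negatives", {
  m <- matrix(c(1000, 1, 0, 100), 2, 2)
  lg <- log10_transform(m)
  expect_equal(lg[1, 1], 3)
  expect_equal(lg[2, 1], 0)
  expect_true(is.na(lg[1, 2]))
  expect_error(log10_transform(matrix(-1)), "negative")
  x <- matrix(stats::runif(50, 0.1, 1e6), 5)
  expect_equal(10^log10_transform(x), x, tolerance = 1e-12)
})

test_that("two-step normalization removes batch structure", {
  cfg <- small_cfg(n_features = 30, n_per_group = 40, planted = integer(0),
                   batch_sd = 0.3, n_batches = 4, seed = 21)
  coh <- generate_cohort(cfg)
  refs <- coh$features$feature_id[coh$features$channel == "heavy"]
  lg <- log10_transform(coh$areas)
  norm <- normalize_two_step(lg, refs, coh$samples)

  # per-feature batch medians equal across batches after Step 2
  for (j in sample(rownames(norm), 5)) {
    med <- tapply(norm[j, ], coh$samples$batch, median)
    expect_lt(max(med) - min(med), 1e-9)
  }

  # between-batch variance component of null features drops > 95%
  bio <- !coh$samples$is_qc
  bvar <- function(m) {
    mean(apply(m[1:30, bio], 1, function(v) {
      stats::var(tapply(v, coh$samples$batch[bio], mean))
    }))
  }
  expect_lt(bvar(norm) / bvar(lg), 0.05)

  # Step 1 alone is a per-sample constant shift: rank-preserving within
  # every sample
  step1 <- normalize_two_step(lg, refs, coh$samples, steps = "longitudinal")
  for (s in sample(colnames(lg), 5)) {
    shift <- lg[, s] - step1[, s]
    expect_lt(diff(range(shift)), 1e-9)
    expect_equal(rank(step1[1:30, s]), rank(lg[1:30, s]))
  }

  # Step 2 preserves each feature's grand median and is idempotent
  step2 <- normalize_two_step(lg, refs, coh$samples, steps = "transverse")
  expect_equal(apply(step2, 1, median), apply(lg, 1, median),
               tolerance = 1e-9)
  step2b <- normalize_two_step(step2, refs, coh$samples, steps = "transverse")
  expect_equal(step2b, step2, tolerance = 1e-9)

  # QC replicate CV (linear scale) does not increase under normalization
  qc <- coh$samples$is_qc
  cv <- function(m) mean(apply(10^m[1:30, qc], 1,
                               function(v) sd(v) / mean(v)))
  expect_lte(cv(norm), cv(lg) + 1e-12)
})

test_that("degenerate normalization cases collapse to shifts", {
  # single batch, constant reference features: Step 1 is a per-sample
  # constant shift, Step 2 centering is idempotent
  set.seed(5)
  m <- rbind(matrix(rnorm(40, 5), 4, 10), REF = 5)
  rownames(m) <- c(paste0("f", 1:4), "REF")
  colnames(m) <- paste0("s", 1:10)
  samples <- data.frame(sample_id = colnames(m), batch = 1,
                        is_qc = rep(c(TRUE, FALSE), c(2, 8)))
  norm <- normalize_two_step(m, "REF", samples)
  # constant references => Step 1 shift is zero; Step 2 equalizes batch
  # medians trivially (one batch) so differences from input are per-
  # feature constants
  d <- norm - m
  expect_true(all(abs(d - rowMeans(d)) < 1e-9))
  expect_error(normalize_two_step(m, "nope", samples), "absent")
})

test_that("SIL quantification follows the internal-standard formula", {
  q <- quantify_sil(2000, 1000, 10)
  expect_equal(q$c_endogenous, 20)
  expect_equal(q$log2_ratio, 1)
  expect_equal(quantify_sil(500, 500, 3)$log2_ratio, 0)
  # scale invariance of the ratio
  q2 <- quantify_sil(2000 * 7, 1000 * 7, 10)
  expect_equal(q2$c_endogenous, q$c_endogenous)
  expect_error(quantify_sil(10, 0, 1), "positive")
  # consistency invariant
  expect_equal(q$c_endogenous, q$c_sis * q$area_endogenous / q$area_sis,
               tolerance = 1e-9)
})
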