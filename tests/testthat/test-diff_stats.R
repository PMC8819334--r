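test_that("Mann-Whitney exact p matches full enumeration", {
  r <- mann_whitney_u(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.100)
  expect_equal(mann_whitney_u(c(2, 4, 6), c(2, 4, 6))$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")

  set.seed(17)
  for (i in 1:30) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    x <- sample(1:100, m); y <- sample(setdiff(1:100, x), n)  # no ties
    expect_equal(mann_whitney_u(x, y)$p, enum_mw_p(x, y), tolerance = 1e-12)
  }

  # invariance under strictly monotone transforms of the pooled data
  x <- rnorm(8); y <- rnorm(9) + 1
  expect_equal(mann_whitney_u(exp(x), exp(y))$p, mann_whitney_u(x, y)$p)
})

test_that("Welch t-test handles degenerate and powered cases", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_true(welch_t_test(c(2, 2), c(2, 2))$degenerate)

  # type-I error at alpha = 0.05 under the null
  set.seed(23)
  rej <- mean(vapply(1:1000, function(i) {
    welch_t_test(rnorm(10), rnorm(10))$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 0.02)

  # large shift: overwhelming evidence
  set.seed(24)
  expect_lt(welch_t_test(rnorm(20, 3), rnorm(20))$p, 1e-6)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, stepup_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) > -1e-12))  # monotone in p
    # permutation invariance
    perm <- sample(length(p))
    expect_equal(benjamini_hochberg(p[perm]), adj[perm])
  }
})

test_that("fold change and volcano classification apply the cutoffs", {
  expect_equal(fold_change(c(2, 4), c(1, 2))$fc, 2)
  eq <- fold_change(c(3, 5), c(3, 5))
  expect_equal(eq$fc, 1); expect_equal(eq$log2_fc, 0)
  expect_equal(fold_change(c(9), c(3))$fc * fold_change(c(3), c(9))$fc, 1)
  expect_error(fold_change(1:3, c(0, 0)), "positive")

  # serum thresholds: 1.5-fold with BH-adjusted p < 0.05
  expect_equal(volcano_classify(0.9, 0.01, adjust = "none"), "up")
  expect_equal(volcano_classify(0.3, 0.001, adjust = "none"), "ns")
  toy_lfc <- c(1.2, -0.8, 0.2, -2, 0.7, 0.59)
  toy_p <- c(0.001, 0.02, 0.001, 0.2, 0.03, 0.01)
  expect_equal(volcano_classify(toy_lfc, toy_p, log2_cutoff = 0.585,
                                p_cutoff = 0.05, adjust = "none"),
               c("up", "down", "ns", "ns", "up", "up"))
  # tissue convention: |log2 FC| >= 1, raw p
  expect_equal(volcano_classify(toy_lfc, toy_p, log2_cutoff = 1,
                                adjust = "none"),
               c("up", "ns", "ns", "ns", "ns", "ns"))
})

test_that("OPLS-DA VIP satisfies its normalization and symmetry", {
  set.seed(41)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  X[, 1] <- X[, 1] + 2 * y            # one informative column
  fit <- opls_da(X, y, n_orthogonal = 1)
  expect_equal(sum(fit$vip^2), 10, tolerance = 1e-6)
  expect_equal(names(which.max(fit$vip)), "v1")
  expect_gt(fit$vip[["v1"]], 1)

  # duplicated column receives identical VIP
  X2 <- cbind(X, v1b = X[, 1])
  fit2 <- opls_da(X2, y, n_orthogonal = 1)
  expect_equal(fit2$vip[["v1"]], fit2$vip[["v1b"]], tolerance = 1e-9)

  # n_orthogonal = 0 reduces to plain PLS1 weights
  fit0 <- opls_da(X, y, n_orthogonal = 0)
  Xs <- scale(X); yc <- y - mean(y)
  w <- drop(crossprod(Xs, yc)); w <- w / sqrt(sum(w^2))
  expect_equal(unname(fit0$vip), unname(sqrt(10) * abs(w)), tolerance = 1e-9)

  expect_error(opls_da(X, rep(1, n)), "two classes")
  expect_warning(opls_da(cbind(X, const = 1), y), "constant")
})

test_that("univariate AUC equals the pairwise-comparison oracle", {
  expect_equal(univariate_auc(c(1, 2, 9, 10), c(0, 0, 1, 1)), 1)
  expect_equal(univariate_auc(rep(5, 6), rep(c(0, 1), 3)), 0.5)
  expect_error(univariate_auc(1:4, rep(1, 4)), "both classes")

  set.seed(47)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    v <- sample(1:10, n, replace = TRUE)        # ties likely
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(univariate_auc(v, l), pairwise_auc(v, l), tolerance = 1e-12)
    expect_equal(univariate_auc(v, l) + univariate_auc(-v, l), 1)
  }
})

test_that("the feature-stats table is internally consistent", {
  cfg <- small_cfg(n_features = 15, n_per_group = 25, planted = 1:2,
                   seed = 51)
  coh <- generate_cohort(cfg)
  prep_refs <- coh$features$feature_id[coh$features$channel == "heavy"]
  norm <- normalize_two_step(log10_transform(coh$areas), prep_refs,
                             coh$samples)
  bio <- !coh$samples$is_qc
  ids <- coh$samples$sample_id
  st <- feature_stats(norm[1:15, bio],
                      case_ids = ids[bio & coh$samples$group == "UR"],
                      control_ids = ids[bio & coh$samples$group == "NC"])
  expect_equal(nrow(st), 15)
  expect_true(all(st$adj_p >= st$p - 1e-12))
  expect_equal(st$log2_fc, log2(st$fc))
  expect_equal(sum(st$vip^2), 15, tolerance = 1e-6)
  expect_true(all(st$auc >= 0 & st$auc <= 1))
})
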