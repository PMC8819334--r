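test_that("tryptic digestion follows the K/R-not-before-P rule", {
  expect_identical(digest("MAGICKEYSRPELLK"), c("MAGICK", "EYSRPELLK"))
  expect_identical(digest("AAAQQQ"), "AAAQQQ")
  expect_error(digest("AAXQQ"), "non-standard residue 'X'")

  # partition property: 0-missed products reconstruct the input
  set.seed(42)
  for (s in random_peptides(25, c(10, 60), seed = 42)) {
    expect_identical(paste(digest(s), collapse = ""), s)
  }

  # idempotence: digesting any fully cleaved product returns itself
  for (pep in digest("MAGICKEYSRPELLKTRIALRKPQD")) {
    expect_identical(digest(pep), pep)
  }

  # missed cleavages: all products with 0..m internal sites
  out <- digest("AAKGGKCC", missed = 1)
  expect_setequal(out, c("AAK", "GGK", "CC", "AAKGGK", "GGKCC"))
})

test_that("monoisotopic peptide mass matches the residue table", {
  expect_equal(peptide_mass("PEPTIDE"), 799.3600, tolerance = 0.0005)
  expect_equal(peptide_mass("G"), 75.0320, tolerance = 0.0005)
  expect_error(peptide_mass(""), "empty")

  # additivity over concatenation minus one water
  for (i in 1:10) {
    ab <- random_peptides(2, c(4, 12), seed = i)
    expect_equal(peptide_mass(paste0(ab[1], ab[2])),
                 peptide_mass(ab[1]) + peptide_mass(ab[2]) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("proteotypic filtering applies rules in fixed order", {
  peps <- data.frame(
    protein = c("P1", "P1", "P2", "P3"),
    sequence = c("ACDEFK", "LLVGPCGAGK", "LLVGPGGAGK", "TTTTTTTTTTK"))
  happy <- function(seqs) {
    data.frame(sequence = seqs, detectability = 0.9, irt = 50)
  }
  res <- filter_ptps(peps, predictor = happy)
  expect_equal(res$rejected$reason[res$rejected$sequence == "ACDEFK"],
               "length")                       # length 6 < 7, before residue rule
  expect_equal(res$rejected$reason[res$rejected$sequence == "LLVGPCGAGK"],
               "forbidden_residue")            # cysteine
  expect_true("LLVGPGGAGK" %in% res$accepted$sequence)
  expect_true("TTTTTTTTTTK" %in% res$accepted$sequence)
  expect_setequal(res$uncovered, "P1")

  # accepted and rejected partition the input
  expect_equal(nrow(res$accepted) + nrow(res$rejected), nrow(peps))

  # shared peptide is rejected as not_unique before any other rule fires
  shared <- data.frame(protein = c("P1", "P2"),
                       sequence = c("SHAREDPEPK", "SHAREDPEPK"))
  res2 <- filter_ptps(shared, predictor = happy)
  expect_true(all(res2$rejected$reason == "not_unique"))

  # low detectability rejected with its own reason
  lowdet <- function(seqs) data.frame(sequence = seqs, detectability = 0.3,
                                      irt = 50)
  res3 <- filter_ptps(data.frame(protein = "P", sequence = "LLVGPGGAGK"),
                      predictor = lowdet)
  expect_equal(res3$rejected$reason, "detectability")

  # at most two accepted peptides per protein, highest detectability
  many <- data.frame(protein = "P",
                     sequence = c("AAAAAAAK", "GGGGGGGK", "VVVVVVVK"))
  graded <- function(seqs) data.frame(sequence = seqs,
                                      detectability = c(0.6, 0.9, 0.8),
                                      irt = 50)
  res4 <- filter_ptps(many, predictor = graded)
  expect_setequal(res4$accepted$sequence, c("GGGGGGGK", "VVVVVVVK"))
})

test_that("precursor charge selection stays in the scan range", {
  p2 <- select_precursor(2000)
  expect_equal(p2$charge, 2)
  expect_equal(p2$mz, 1001.0073, tolerance = 0.001)
  p3 <- select_precursor(2600)           # z=2 would be 1301 > 1250
  expect_equal(p3$charge, 3)
  expect_equal(p3$mz, 867.6739, tolerance = 0.001)
  expect_null(select_precursor(120))     # all m/z below 350
})

test_that("transition selection ranks eligible fragments by intensity", {
  lib <- data.frame(series = c("y", "y", "b", "y", "b", "y"),
                    ordinal = c(4, 3, 2, 7, 5, 1),
                    intensity = c(100, 90, 80, 70, 60, 50))
  sel <- select_transitions(lib, k = 3)
  expect_equal(paste0(sel$series, sel$ordinal), c("y4", "y7", "b5"))

  short <- data.frame(series = c("y", "b"), ordinal = c(2, 1),
                      intensity = c(100, 90))
  expect_null(select_transitions(short))
  expect_error(select_transitions(data.frame()), "empty")

  # brute force: selected intensities are the k largest among eligible
  set.seed(9)
  for (i in 1:20) {
    lib <- data.frame(series = sample(c("b", "y"), 10, TRUE),
                      ordinal = sample(1:9, 10, TRUE),
                      intensity = stats::runif(10, 1, 100))
    elig <- lib$intensity[lib$ordinal >= 4]
    sel <- select_transitions(lib, k = 3)
    if (length(elig) < 3) {
      expect_null(sel)
    } else {
      expect_equal(sort(sel$intensity, decreasing = TRUE),
                   sort(elig, decreasing = TRUE)[1:3])
    }
  }
})

test_that("scheduled windows are centered, clipped and audited", {
  s <- build_schedule(c(a = 20), width = 3)
  expect_equal(c(s$start, s$end), c(18.5, 21.5))
  s2 <- build_schedule(c(a = 1), width = 3, gradient = c(0, 60))
  expect_equal(c(s2$start, s2$end), c(0, 2.5))
  expect_error(build_schedule(c(1, NA)), "missing retention-time")

  # interval-overlap oracle for the reported max concurrency
  set.seed(11)
  for (i in 1:10) {
    rt <- stats::runif(30, 0, 65)
    s <- build_schedule(rt, width = 3, gradient = c(0, 65))
    expect_equal(attr(s, "max_concurrent"),
                 sweep_max_concurrent(s$start, s$end))
  }
})

test_that("heuristic predictor is deterministic with valid codomain", {
  peps <- random_peptides(200, seed = 3)
  p1 <- heuristic_predictor(peps)
  p2 <- heuristic_predictor(peps)
  expect_identical(p1, p2)
  expect_true(all(p1$detectability >= 0 & p1$detectability <= 1))
  # hydropathy ordering on iRT
  expect_gt(heuristic_predictor("LLLLLLLL")$irt,
            heuristic_predictor("DDDDDDDD")$irt)
})

test_that("designed assays satisfy every assay invariant", {
  prot <- generate_proteome(30, seed = 2)
  peps <- unique(unlist(lapply(as.character(prot), digest)))
  lib <- simulate_spectral_library(peps, seed = 2)
  des <- design_assays(prot, lib)
  a <- des$assays
  expect_gt(nrow(a), 0)
  expect_true(all(a$precursor_mz >= 350 & a$precursor_mz <= 1250))
  for (i in seq_len(nrow(a))) {
    tr <- a$transitions[[i]]
    expect_gte(nrow(tr), 3)
    expect_true(all(tr$ordinal >= 4))
  }
  expect_true(all(abs((a$window_end - a$window_start) - 3) < 1e-9 |
                    a$window_start == 0 | abs(a$window_end - 65) < 1e-9))
  # accepted peptides obey the PTP rules
  expect_true(all(nchar(a$sequence) >= 7 & nchar(a$sequence) <= 25))
  expect_true(all(a$mass <= 6000))
  expect_true(all(a$detectability > 0.5))
  expect_false(any(grepl("[MC]", a$sequence)))
})
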