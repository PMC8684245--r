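test_that("polarisation orients the site by the ancestral allele", {
  p <- polarize("A", "G", "A", c(0.3, 0.9))
  expect_equal(p$status, "ok")
  expect_equal(p$daf, c(0.3, 0.9))
  expect_equal(p$derived_allele, "G")

  p <- polarize("A", "G", "G", c(0.3, 0.9))
  expect_equal(p$daf, c(0.7, 0.1))
  expect_equal(p$derived_allele, "A")

  expect_equal(polarize("A", "G", "T", c(0.3, 0.9))$reason, "AA_MISMATCH")
  for (miss in list(NA_character_, ".", "-", "N"))
    expect_equal(polarize("A", "G", miss, c(0.5, 0.5))$reason, "AA_MISSING")
})

test_that("lowercase ancestral calls follow the confidence policy", {
  relaxed <- polarize("A", "G", "a", c(0.2, 0.8))
  expect_equal(relaxed$status, "ok")
  expect_true(relaxed$low_confidence)
  expect_equal(relaxed$daf, c(0.2, 0.8))
  strict <- polarize("A", "G", "a", c(0.2, 0.8), strict_ancestral = TRUE)
  expect_equal(strict$reason, "AA_LOW_CONFIDENCE")
})

test_that("polarisation under opposite ancestral assignments is complementary", {
  set.seed(5)
  for (i in 1:25) {
    af <- round(runif(3), 3)
    as_ref <- polarize("C", "T", "C", af)
    as_alt <- polarize("C", "T", "T", af)
    expect_equal(as_ref$daf + as_alt$daf, c(1, 1, 1))
    expect_equal(as_ref$derived_allele, "T")
    expect_equal(as_alt$derived_allele, "C")
  }
})

test_that("derived allele purity matches closed forms and frozen values", {
  # population-specific derived allele: purity 1 regardless of x
  expect_equal(compute_dap(c(1, 0, 0), 3.5), 1)
  expect_equal(compute_dap(c(0, 0.37, 0), 8), 1)
  # equal sharing: closed form n^(1 - x)
  expect_equal(compute_dap(c(0.5, 0.5), 4.96), 2^(1 - 4.96))
  expect_equal(compute_dap(rep(0.8, 3), 3.5), 3^(1 - 3.5))
  # worked example, frozen from the naive oracle
  expect_equal(compute_dap(c(0.922, 0.029, 0.490), 3.5), 0.2324532024,
               tolerance = 1e-9)
  # derived allele absent everywhere: defined as 0
  expect_equal(compute_dap(c(0, 0, 0), 3.5), 0)
  # matrix form agrees with the vector form row by row
  m <- rbind(c(0.922, 0.029, 0.490), c(1, 0, 0), c(0, 0, 0))
  expect_equal(compute_dap(m, 3.5),
               c(compute_dap(m[1, ], 3.5), 1, 0))
})

test_that("purity input contracts are enforced", {
  expect_error(compute_dap(c(0.5, 1.2), 3.5), "\\[0, 1\\]")
  expect_error(compute_dap(c(-0.1, 0.5), 3.5), "\\[0, 1\\]")
  expect_error(compute_dap(c(0.5, 0.5), 1), "exceed 1")
  expect_error(polarize("A", "A", "A", c(0.5)), "differ")
})

test_that("score is the exact product DAP x DAF x CADD", {
  daf <- c(0.922, 0.029, 0.490)
  s <- compute_scores(daf, cadd_phred = 20, x = 3.5)
  expect_equal(s$finemav, s$dap * daf * 20)  # algebraic identity
  expect_equal(s$finemav, c(4.28643705, 0.13482286, 2.27804138),
               tolerance = 1e-8)
  # multiplicative zero and the dap = 1 single-carrier case
  expect_equal(compute_scores(daf, 0, 3.5)$finemav, c(0, 0, 0))
  s1 <- compute_scores(c(0, 0.37, 0), 15, 3.5)
  expect_equal(s1$finemav, c(0, 1 * 0.37 * 15, 0))
  expect_error(compute_scores(daf, NA, 3.5), "required")
})

test_that("purity is permutation-invariant and decreases with the penalty", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:6, 1)
    daf <- round(runif(n), 3)
    x <- runif(1, 1.1, 6)
    dap <- compute_dap(daf, x)
    expect_gte(dap, 0)
    expect_lte(dap, 1 + 1e-12)
    if (sum(daf) > 0) expect_gte(dap, n^(1 - x) - 1e-12)
    expect_equal(compute_dap(sample(daf), x), dap)
    if (sum(daf > 0) >= 2) {
      expect_lt(compute_dap(daf, x + 0.5), dap)  # strict decrease
    } else if (sum(daf > 0) == 1) {
      expect_equal(compute_dap(daf, x + 0.5), 1)
    }
  }
})

test_that("purity is 1 exactly when one population carries the derived allele", {
  set.seed(8)
  for (i in 1:30) {
    daf <- numeric(4)
    k <- sample(1:4, sample(1:4, 1))
    daf[k] <- runif(length(k), 0.05, 1)
    dap <- compute_dap(daf, 2.98)
    if (length(k) == 1) expect_equal(dap, 1)
    else expect_lt(dap, 1)
  }
})

test_that("vectorised scoring applies the filter policy per site", {
  panel <- population_panel(c("P1", "P2"))
  recs <- data.table::data.table(
    chrom = "1", pos = 1:5 * 10L, id = paste0("s", 1:5),
    ref = "A", alt = "G",
    aa = c("A", "G", "T", ".", "A"),
    cadd_phred = c(10, 10, 10, 10, NA),
    af_1 = c(0.2, 0.2, 0.2, 0.2, 0.2),
    af_2 = c(0.9, 0.9, 0.9, 0.9, 0.9))
  out <- score_sites(recs, panel, x = 4.96)
  expect_equal(nrow(out$scores), 2L)
  expect_equal(out$rejects$reason,
               c("AA_MISMATCH", "AA_MISSING", "CADD_MISSING"))
  # site 1: aa == ref; site 2: aa == alt (complementary daf)
  expect_equal(out$scores$daf_P1, c(0.2, 0.8))
  expect_equal(out$scores$daf_P2, c(0.9, 0.1))
  expect_equal(out$scores$derived_allele, c("G", "A"))
  # per-site identity: finemav_i / daf_i is constant where daf_i > 0
  with(out$scores[1], {
    expect_equal(finemav_P1 / daf_P1, finemav_P2 / daf_P2)
    expect_equal(finemav_P1, dap * daf_P1 * cadd_phred)
  })
  expect_equal(ncol(out$scores), 9 + 2 * panel$n)
})
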