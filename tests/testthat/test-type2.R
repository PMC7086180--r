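test_that("fully conserved alignment gives theta2 = 0 with zero posteriors", {
  aln <- toyAlignment(rep("ACDEFGHIKL", 3), rep("ACDEFGHIKL", 3))
  res <- type2Divergence(aln, "m", "s")
  expect_equal(theta2(res), 0)
  expect_equal(zScore(res), 0)
  expect_true(all(sitePosteriors(res) == 0))
  expect_true(all(sitePatterns(res) == "conserved_same_residue"))
})

test_that("clean divergent sites are detected with high posteriors", {
  # site 1 radical between clades (D/E acidic vs K/R basic), conserved
  # within; sites 2-10 identical everywhere
  aln <- toyAlignment(rep("DAAAAAAAAA", 3), rep("KAAAAAAAAA", 3))
  res <- type2Divergence(aln, "m", "s")
  expect_equal(theta2(res), 0.1, tolerance = 1e-9)
  expect_identical(sitePatterns(res)[1], "candidate")
  expect_gt(sitePosteriors(res)[1], 0.9)
  expect_true(all(sitePosteriors(res)[-1] == 0))
})

test_that("theta2 recovers the simulated divergent fraction", {
  theta <- vapply(1:8, function(i) {
    aln <- simulateCladeAlignment(SimConfig(seed = 400 + i, nSites = 400,
                                            propType2 = 0.3))
    theta2(type2Divergence(aln, "mammal", "sauropsid"))
  }, numeric(1))
  expect_lt(abs(mean(theta) - 0.3), 0.05)
})

test_that("theta2 is monotone in the simulated divergence level", {
  means <- vapply(c(0, 0.1, 0.3, 0.5), function(p) {
    mean(vapply(1:5, function(i) {
      aln <- simulateCladeAlignment(SimConfig(seed = 900 + i, nSites = 300,
                                              propType2 = p))
      theta2(type2Divergence(aln, "mammal", "sauropsid"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_true(all(means >= 0 & means <= 1))
})

test_that("truth sites outrank background sites by posterior", {
  aln <- simulateCladeAlignment(SimConfig(seed = 77, nSites = 400,
                                          propType2 = 0.2))
  res <- type2Divergence(aln, "mammal", "sauropsid")
  truth <- seq_len(400) %in% type2Sites(aln)
  expect_gt(auroc(sitePosteriors(res), truth), 0.95)
})

test_that("coverage filtering and degenerate inputs error as specified", {
  # variable everywhere -> no conserved site
  aln <- toyAlignment(c("AD", "CE", "GK"), c("HP", "LR", "MS"))
  expect_error(type2Divergence(aln, "m", "s"), "conserved within both")
  # clade with < 2 taxa
  aln2 <- toyAlignment(c("AAAA"), c("AAAA", "AAAA"))
  expect_error(type2Divergence(aln2, "m", "s"), "at least 2 taxa")
  # low-coverage site is excluded from the pattern record
  alnX <- toyAlignment(c("XAAAA", "AAAAA", "-AAAA"),
                       c("AAAAA", "XAAAA", "AAAAA"))
  res <- type2Divergence(alnX, "m", "s", coverage = 0.95)
  expect_identical(sitePatterns(res)[1], "excluded")
  expect_true(is.na(sitePosteriors(res)[1]))
})

test_that("z equals theta2/se and the null rarely reaches significance", {
  zs <- vapply(1:20, function(i) {
    aln <- simulateCladeAlignment(SimConfig(seed = 2000 + i, nSites = 300,
                                            propType2 = 0))
    r <- type2Divergence(aln, "mammal", "sauropsid")
    if (r@se > 0) expect_equal(zScore(r), theta2(r) / r@se, tolerance = 1e-12)
    zScore(r)
  }, numeric(1))
  expect_lte(mean(zs > 1.64), 0.10)
})
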