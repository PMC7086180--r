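test_that("library-size factors: closed forms and error handling", {
  m <- matrix(c(60, 40, 240, 160), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(computeSizeFactors(m), c(a = 0.5, b = 2))
  eq <- matrix(5L, 4, 3, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(unname(computeSizeFactors(eq)), rep(1, 3))
  # mean of log factors is zero by construction
  set.seed(1)
  r <- matrix(rpois(600, 20), 20)
  colnames(r) <- paste0("c", 1:30)
  expect_equal(mean(log(computeSizeFactors(r))), 0, tolerance = 1e-12)
  bad <- cbind(r, empty = 0L)
  expect_error(computeSizeFactors(bad), "empty")
})

test_that("size factors recover simulated truth", {
  set.seed(33)
  mm <- matrix(10^runif(1000, 0, 3), 1000, 1,
               dimnames = list(paste0("g", 1:1000), "tA"))
  sce <- simulateCounts(SimConfig(seed = 33, nCellsPerType = 200), mm)
  sf <- computeSizeFactors(SummarizedExperiment::assay(sce, "counts"))
  rho <- cor(sf, sce$sizeFactorTruth, method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("single EM E-step responsibilities match hand computation", {
  # 2 genes x 3 cells, unit size factors; freeze the model parameters and
  # verify the dropout responsibilities against the mixture formula
  k <- matrix(c(0L, 5L, 1L, 30L, 0L, 28L), 2, 3,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  mid <- 0.5; slope <- 1.5; r <- 2; lam <- 0.1
  mg <- c(2, 25)
  pd <- dropoutProbability(mg, mid, slope)
  zHand <- matrix(0, 2, 3)
  for (g in 1:2) for (cc in 1:3) {
    num <- pd[g] * dpois(k[g, cc], lam)
    den <- num + (1 - pd[g]) * dnbinom(k[g, cc], mu = mg[g], size = r)
    zHand[g, cc] <- num / den
  }
  z <- nachrevo:::.dropoutResponsibility(k, matrix(mg, 2, 3),
                                         matrix(1, 2, 3), mid, slope, r, lam)
  expect_equal(unname(z), zHand, tolerance = 1e-12)
})

test_that("no-dropout data yields a near-zero fitted dropout curve", {
  set.seed(9)
  mm <- matrix(10^runif(200, 0.5, 3), 200, 1,
               dimnames = list(paste0("g", 1:200), "tA"))
  sce <- simulateCounts(SimConfig(seed = 9, nCellsPerType = 100,
                                  dropoutMidpoint = -Inf), mm)
  em <- suppressWarnings(fitErrorModel(sce))
  pd <- dropoutProbability(mm[, 1], em@dropoutMidpoint[1], em@dropoutSlope[1])
  expect_lt(max(pd), 0.05)
})

test_that("EM recovers NB size and dropout midpoint", {
  fits <- vapply(1:4, function(i) {
    set.seed(600 + i)
    mm <- matrix(10^runif(300, -1, 3), 300, 1,
                 dimnames = list(paste0("g", 1:300), "tA"))
    sce <- simulateCounts(SimConfig(seed = 600 + i, nCellsPerType = 120,
                                    nbSize = 2, dropoutMidpoint = 0.5), mm)
    em <- suppressWarnings(fitErrorModel(sce))
    c(em@nbSize, em@dropoutMidpoint[1])
  }, numeric(2))
  expect_lt(abs(mean(fits[1, ]) / 2 - 1), 0.3)
  expect_lt(abs(mean(fits[2, ]) - 0.5), 0.3)
})

test_that("grid posterior equals a direct per-point product", {
  k <- matrix(c(3L, 12L, 0L), 1, 3,
              dimnames = list("g1", paste0("c", 1:3)))
  sf <- c(0.8, 1, 1.4)
  em <- new("ExpressionErrorModel", dropoutMidpoint = rep(0.5, 3),
            dropoutSlope = rep(1.5, 3), nbSize = 2, dropoutLambda = 0.1,
            converged = TRUE, nIter = 1L)
  grid <- 10^seq(-1, 2, length.out = 40)
  post <- posteriorExpression(k, em, sizeFactors = sf, grid = grid)
  direct <- vapply(grid, function(m) {
    pd <- dropoutProbability(m, 0.5, 1.5)
    prod(pd * dpois(k[1, ], 0.1) + (1 - pd) * dnbinom(k[1, ], mu = m * sf,
                                                      size = 2))
  }, numeric(1))
  direct <- direct / sum(direct)
  expect_equal(unname(posteriorWeights(post)[1, ]), direct,
               tolerance = 1e-9)
  expect_equal(sum(posteriorWeights(post)[1, ]), 1, tolerance = 1e-9)
})

test_that("posterior mode and degenerate inputs behave as expected", {
  # one cell, near-Poisson NB, no dropout, k = 10 -> mode near 10
  k <- matrix(10L, 1, 1, dimnames = list("g", "c"))
  em <- new("ExpressionErrorModel", dropoutMidpoint = -20,
            dropoutSlope = 1, nbSize = 1e6, dropoutLambda = 0.1,
            converged = TRUE, nIter = 1L)
  post <- posteriorExpression(k, em, sizeFactors = 1)
  mode <- posteriorGrid(post)[which.max(posteriorWeights(post)[1, ])]
  expect_equal(log10(mode), 1, tolerance = 0.02)

  # all-zero gene with moderate dropout: mass at the grid floor
  k0 <- matrix(0L, 1, 30, dimnames = list("g", paste0("c", 1:30)))
  em0 <- new("ExpressionErrorModel", dropoutMidpoint = rep(0.5, 30),
             dropoutSlope = rep(1.5, 30), nbSize = 2, dropoutLambda = 0.1,
             converged = TRUE, nIter = 1L)
  p0 <- posteriorExpression(k0, em0, sizeFactors = rep(1, 30))
  expect_lt(posteriorMean(p0)[1], 10 * min(posteriorGrid(p0)))
})

test_that("posterior means track simulated truth across genes", {
  set.seed(55)
  mm <- matrix(10^runif(250, -1, 3), 250, 1,
               dimnames = list(paste0("g", 1:250), "tA"))
  sce <- simulateCounts(SimConfig(seed = 55, nCellsPerType = 80), mm)
  em <- suppressWarnings(fitErrorModel(sce))
  post <- posteriorExpression(sce, em, cellType = "tA")
  rho <- cor(posteriorMean(post), mm[, 1], method = "spearman")
  expect_gt(rho, 0.9)
})
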