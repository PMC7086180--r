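test_that("limit cases: no change and saturation", {
  cfg0 <- SimConfig(seed = 3, nSites = 50, propType2 = 0,
                    withinCladeSubRate = 0)
  aln <- simulateCladeAlignment(cfg0)
  seqs <- as.character(alignedSequences(aln))
  expect_length(unique(seqs), 1)
  expect_length(type2Sites(aln), 0)

  cfg1 <- SimConfig(seed = 3, nSites = 50, propType2 = 1,
                    withinCladeSubRate = 0)
  aln1 <- simulateCladeAlignment(cfg1)
  expect_identical(type2Sites(aln1), 1:50)
  m <- nachrevo:::.alnMatrix(aln1)
  cl <- cladeOf(aln1)
  for (s in 1:50) {
    perClade <- split(m[, s], cl[rownames(m)])
    expect_true(all(lengths(lapply(perClade, unique)) == 1))
    groups <- vapply(perClade, function(x) propertyGroupOf[x[1]], "")
    expect_false(groups[1] == groups[2])
  }
})

test_that("truth sites satisfy the per-site type-II predicate; count is exact", {
  cfg <- SimConfig(seed = 1, nSites = 200, propType2 = 0.2)
  aln <- simulateCladeAlignment(cfg)
  expect_length(type2Sites(aln), 40)   # floor(0.2 * 200)
  m <- nachrevo:::.alnMatrix(aln)
  cl <- cladeOf(aln)
  for (s in type2Sites(aln)) {
    perClade <- split(m[, s], cl[rownames(m)])
    expect_true(all(lengths(lapply(perClade, unique)) == 1),
                info = paste("within-clade monomorphic, site", s))
    groups <- vapply(perClade, function(x) propertyGroupOf[x[1]], "")
    expect_false(groups[1] == groups[2],
                 info = paste("between-clade discordant, site", s))
  }
  # at rate 0 no unlabeled site satisfies the predicate
  cfg0 <- SimConfig(seed = 5, nSites = 120, propType2 = 0.25,
                    withinCladeSubRate = 0)
  aln0 <- simulateCladeAlignment(cfg0)
  m0 <- nachrevo:::.alnMatrix(aln0)
  cl0 <- cladeOf(aln0)
  satisfies <- vapply(seq_len(ncol(m0)), function(s) {
    perClade <- split(m0[, s], cl0[rownames(m0)])
    mono <- all(lengths(lapply(perClade, unique)) == 1)
    if (!mono) return(FALSE)
    groups <- vapply(perClade, function(x) propertyGroupOf[x[1]], "")
    groups[1] != groups[2]
  }, logical(1))
  expect_identical(which(satisfies), as.integer(type2Sites(aln0)))
})

test_that("fixed seed reproduces the alignment bit-identically", {
  cfg <- SimConfig(seed = 11, nSites = 80, propType2 = 0.3)
  a1 <- simulateCladeAlignment(cfg)
  a2 <- simulateCladeAlignment(cfg)
  expect_identical(as.character(alignedSequences(a1)),
                   as.character(alignedSequences(a2)))
  expect_identical(type2Sites(a1), type2Sites(a2))
})

test_that("invalid inputs are rejected", {
  expect_error(simulateCladeAlignment(SimConfig(nTaxaPerClade = 1)),
               "at least 2 taxa")
  expect_error(simulateCladeAlignment(SimConfig(), clades = "one"),
               "2 clades")
  expect_error(SimConfig(propType2 = 1.5), "propType2")
})

test_that("more than two clades get pairwise-distinct groups at truth sites", {
  cfg <- SimConfig(seed = 2, nSites = 60, propType2 = 0.5,
                   withinCladeSubRate = 0)
  aln <- simulateCladeAlignment(cfg, clades = c("m", "s", "a"))
  m <- nachrevo:::.alnMatrix(aln)
  cl <- cladeOf(aln)
  for (s in type2Sites(aln)) {
    groups <- vapply(split(m[, s], cl[rownames(m)]),
                     function(x) propertyGroupOf[x[1]], "")
    expect_equal(length(unique(groups)), 3)
  }
})
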