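test_that("identity arithmetic on small cases", {
  aln <- toyAlignment(c("ACDEF", "ACDEF"), c("ACDFF", "AC-EF"))
  v <- identityValues(pairwiseIdentity(aln))
  expect_equal(v["m1", "m2"], 100)           # identical 5-mers
  expect_equal(v["m1", "s1"], 80)            # 4/5
  expect_equal(v["m1", "s2"], 100)           # 4/4 comparable under pairwise
  expect_equal(diag(v), setNames(rep(100, 4), rownames(v)))
})

test_that("complete deletion removes columns with any gap or X", {
  aln <- toyAlignment(c("ACDEF", "ACDEF"), c("AXDEF", "AC-EF"))
  vc <- identityValues(pairwiseIdentity(aln, mode = "complete"))
  # columns 2 (X in s1) and 3 (gap in s2) removed -> compare on A,E,F
  expect_equal(vc["m1", "s1"], 100)
  vp <- identityValues(pairwiseIdentity(aln, mode = "pairwise"))
  expect_equal(vp["m1", "s1"], 100 * 4 / 4)
})

test_that("pair with no comparable columns is NA, not zero", {
  aln <- toyAlignment(c("AC--"), c("--DE"))
  v <- identityValues(pairwiseIdentity(aln))
  expect_true(is.na(v["m1", "s1"]))
  expect_error(distanceTree(pairwiseIdentity(
    toyAlignment(c("AC--", "ACAA"), c("--DE")))), "complete")
})

test_that("identity is symmetric and invariant to taxon order", {
  cfg <- SimConfig(seed = 6, nSites = 60, propType2 = 0.2, nTaxaPerClade = 3)
  aln <- simulateCladeAlignment(cfg)
  v <- identityValues(pairwiseIdentity(aln))
  expect_identical(v, t(v))
  perm <- rev(seq_along(alignedSequences(aln)))
  alnR <- CladeAlignment(as.character(alignedSequences(aln))[perm],
                         cladeOf(aln)[perm])
  vR <- identityValues(pairwiseIdentity(alnR))
  expect_equal(v[rownames(vR), colnames(vR)], vR)
})

test_that("clade averages equal brute-force means; singleton clade is NA", {
  # constructed 2+2 identity matrix, hand-computable over the <= 6 pairs
  aln <- toyAlignment(c("AAAA", "AAAC"), c("DDDD", "DDDA"))
  im <- pairwiseIdentity(aln)
  avg <- cladeAverageIdentity(im, cladeOf(aln))
  v <- identityValues(im)
  getRow <- function(a, b)
    avg$meanIdentity[avg$cladeA == a & avg$cladeB == b]
  expect_equal(getRow("m", "m"), v["m1", "m2"])
  expect_equal(getRow("s", "s"), v["s1", "s2"])
  expect_equal(getRow("m", "s"),
               mean(c(v["m1", "s1"], v["m1", "s2"],
                      v["m2", "s1"], v["m2", "s2"])))

  # all-identical alignment: every mean 100
  alnI <- toyAlignment(c("AAA", "AAA"), c("AAA", "AAA"))
  avgI <- cladeAverageIdentity(pairwiseIdentity(alnI), cladeOf(alnI))
  expect_true(all(avgI$meanIdentity == 100))

  # singleton clade: within mean missing, between mean defined
  seqs <- c(a = "AAAA", b = "AAAC", c = "DDDD")
  alnS <- CladeAlignment(seqs, c(a = "x", b = "x", c = "lone"))
  avgS <- cladeAverageIdentity(pairwiseIdentity(alnS), c(a = "x", b = "x",
                                                         c = "lone"))
  expect_true(is.na(avgS$meanIdentity[avgS$cladeA == "lone" &
                                        avgS$cladeB == "lone"]))
  expect_false(is.na(avgS$meanIdentity[avgS$cladeA == "x" &
                                         avgS$cladeB == "lone"]))
})
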