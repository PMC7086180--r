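test_that("pruning matches brute-force enumeration on 3- and 4-tip trees", {
  tr3 <- ape::read.tree(text = "(t1:0.3,t2:0.5,t3:0.2);")
  tr4 <- ape::read.tree(text = "((t1:0.2,t2:0.7):0.4,(t3:0.1,t4:0.9):0.3);")
  cases <- list(
    list(tree = tr3, tips = c(t1 = "A", t2 = "A", t3 = "D")),
    list(tree = tr3, tips = c(t1 = "K", t2 = "E", t3 = "W")),
    list(tree = tr4, tips = c(t1 = "A", t2 = "C", t3 = "A", t4 = "A")),
    list(tree = tr4, tips = c(t1 = "R", t2 = "R", t3 = "K", t4 = "H")))
  for (model in c("poisson", "jtt")) {
    for (cs in cases) {
      seqs <- Biostrings::AAStringSet(cs$tips)
      rec <- ancestralSequencesML(seqs, cs$tree, model = model)
      bf <- bruteForceAncestral(cs$tips, cs$tree, model = model)
      expect_equal(rec$siteLogLik[1], log(bf$siteLik), tolerance = 1e-9)
      for (j in seq_along(rec$posteriors))
        expect_equal(unname(rec$posteriors[[j]][1, ]),
                     unname(bf$posteriors[, j]), tolerance = 1e-9)
    }
  }
})

test_that("posteriors sum to one and identical tips pin the ancestor", {
  cfg <- SimConfig(seed = 2, nSites = 40, propType2 = 0.1, nTaxaPerClade = 3)
  aln <- simulateCladeAlignment(cfg)
  tree <- distanceTree(pairwiseIdentity(aln), correction = "poisson")
  tree <- ape::root(tree, names(cladeOf(aln))[1], resolve.root = TRUE)
  rec <- ancestralSequencesML(aln, tree)
  for (p in rec$posteriors)
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)

  # all tips identical at a site: posterior -> 1 as branch lengths -> 0
  short <- ape::read.tree(text = "(t1:1e-6,t2:1e-6,t3:1e-6);")
  rec1 <- ancestralSequencesML(Biostrings::AAStringSet(
    c(t1 = "W", t2 = "W", t3 = "W")), short)
  expect_identical(unname(rec1$states[1, 1]), "W")
  expect_gt(rec1$posteriors[[1]][1, "W"], 1 - 1e-4)
})

test_that("zero-length tree with conflicting tips errors; missing leaf errors", {
  zero <- ape::read.tree(text = "(t1:0,t2:0,t3:0);")
  expect_error(ancestralSequencesML(Biostrings::AAStringSet(
    c(t1 = "A", t2 = "D", t3 = "A")), zero), "zero-length")
  tr <- ape::read.tree(text = "(t1:0.1,t2:0.1,tX:0.1);")
  expect_error(ancestralSequencesML(Biostrings::AAStringSet(
    c(t1 = "A", t2 = "D")), tr), "missing from the alignment")
})

test_that("missing data contributes no information", {
  tr <- ape::read.tree(text = "(t1:0.2,t2:0.2,t3:0.2);")
  full <- ancestralSequencesML(Biostrings::AAStringSet(
    c(t1 = "A", t2 = "A", t3 = "X")), tr)
  two <- ancestralSequencesML(Biostrings::AAStringSet(
    c(t1 = "A", t2 = "A", t3 = "-")), tr)
  expect_equal(full$posteriors[[1]], two$posteriors[[1]], tolerance = 1e-12)
})

test_that("discrete-gamma rate variation still matches a mixture oracle", {
  tr <- ape::read.tree(text = "(t1:0.3,t2:0.5,t3:0.2);")
  tips <- c(t1 = "A", t2 = "A", t3 = "D")
  rec <- ancestralSequencesML(Biostrings::AAStringSet(tips), tr,
                              gammaAlpha = 0.7)
  rates <- phangorn::discrete.gamma(0.7, 4)
  liks <- post <- 0
  for (rr in rates) {
    scaled <- tr; scaled$edge.length <- tr$edge.length * rr
    bf <- bruteForceAncestral(tips, scaled)
    liks <- liks + bf$siteLik / 4
    post <- post + bf$posteriors[, 1] * bf$siteLik / 4
  }
  expect_equal(rec$siteLogLik[1], log(liks), tolerance = 1e-9)
  expect_equal(unname(rec$posteriors[[1]][1, ]), unname(post / liks),
               tolerance = 1e-9)
})
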