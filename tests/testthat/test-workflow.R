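smallConfig <- function(dir, stages = NULL) {
  cfg <- list(
    seed = 42,
    outputDir = dir,
    parameters = list(sim = list(nSites = 80, propType2 = 0.2,
                                 nTaxaPerClade = 4, nCellsPerType = 25)))
  if (!is.null(stages)) cfg$stages <- stages
  cfg
}

test_that("config validation fails fast on missing inputs", {
  expect_error(validatePipelineConfig(
    list(stages = list(synthetic = FALSE, coexpression = TRUE))),
    "countsPath")
  expect_error(validatePipelineConfig(
    list(stages = list(synthetic = FALSE, seqdiv = TRUE,
                       coexpression = FALSE))),
    "alignmentFasta")
  expect_error(validatePipelineConfig(
    list(inputs = list(propertyTable = "no/such/file.tsv"))),
    "not found")
  expect_error(validatePipelineConfig("no/such/config.yaml"), "not found")
})

test_that("a fixed seed reproduces the manifest checksums", {
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  m1 <- suppressWarnings(suppressMessages(runPipeline(smallConfig(d1))))
  m2 <- suppressWarnings(suppressMessages(runPipeline(smallConfig(d2))))
  expect_identical(m1$outputs, m2$outputs)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # key outputs exist
  expect_true(file.exists(file.path(d1, "seqdiv", "type2_summary.tsv")))
  expect_true(file.exists(file.path(d1, "functional", "pca_variance.tsv")))
  expect_true(file.exists(file.path(d1, "coexpression",
                                    "repertoire_calls.tsv")))
})

test_that("disabling a stage leaves the other outputs byte-identical", {
  dA <- file.path(tempdir(), "runA"); dB <- file.path(tempdir(), "runB")
  on.exit(unlink(c(dA, dB), recursive = TRUE))
  suppressWarnings(suppressMessages(runPipeline(smallConfig(dA))))
  cfgB <- smallConfig(dB, stages = list(synthetic = TRUE, seqdiv = TRUE,
                                        coexpression = FALSE,
                                        functional = TRUE))
  suppressWarnings(suppressMessages(runPipeline(cfgB)))
  for (rel in c("seqdiv/type2_summary.tsv", "seqdiv/identity.tsv",
                "functional/pca_variance.tsv",
                "synthetic/alignment.fasta")) {
    expect_identical(unname(tools::md5sum(file.path(dA, rel))),
                     unname(tools::md5sum(file.path(dB, rel))),
                     info = rel)
  }
  expect_false(dir.exists(file.path(dB, "coexpression")))
})

test_that("the packaged property-table run yields PCA and projections", {
  d <- file.path(tempdir(), "runF")
  on.exit(unlink(d, recursive = TRUE))
  cfg <- list(seed = 1, outputDir = d,
              stages = list(synthetic = FALSE, seqdiv = FALSE,
                            coexpression = FALSE, functional = TRUE))
  m <- suppressWarnings(suppressMessages(runPipeline(cfg)))
  v <- utils::read.delim(file.path(d, "functional", "pca_variance.tsv"))
  expect_equal(sum(v$varianceFraction), 1, tolerance = 1e-9)
  expect_lt(abs(100 * sum(v$varianceFraction[1:2]) - 82), 3)
  proj <- utils::read.delim(file.path(d, "functional",
                                      "ancestral_projection.tsv"),
                            row.names = 1)
  expect_equal(nrow(proj), 6)   # amniote + tetrapod x 3 receptor subtypes
  expect_equal(colnames(proj), c("PC1", "PC2"))
})
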