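#' @import methods
#' @importFrom stats setNames
NULL

# Fixed 20-letter amino-acid alphabet; also the tie-break order for argmax
# ancestral states. Gap '-' and missing 'X' are treated as missing data
# throughout.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Charge-first biochemical property partition used for "radical" changes:
# acidic, basic, polar/other, hydrophobic.
DEFAULT_PROPERTY_GROUPS <- list(
  acidic      = c("D", "E"),
  basic       = c("K", "R", "H"),
  polar       = c("S", "T", "N", "Q", "C", "G", "P", "Y"),
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W")
)

#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the three generators: clade-structured alignments
#' with a controllable fraction of divergent sites, negative-binomial counts
#' with expression-dependent dropout, and Brownian-motion traits on a tree.
#'
#' @slot seed integer seed; a fixed seed gives bit-identical outputs.
#' @slot nTaxaPerClade taxa simulated per clade (>= 2).
#' @slot nSites alignment length in amino-acid sites.
#' @slot propType2 fraction in [0,1] of sites carrying a between-clade
#'   radical property change while conserved within each clade.
#' @slot withinCladeSubRate per-taxon, per-site substitution probability for
#'   the background (non-divergent) sites.
#' @slot nCellsPerType cells simulated per cell type.
#' @slot nbSize negative-binomial size (dispersion) parameter r.
#' @slot dropoutLambda mean of the low-magnitude Poisson drawn on dropout.
#' @slot dropoutMidpoint log10 expression at which dropout probability is 0.5.
#' @slot dropoutSlope logistic slope (per log10 unit) of the dropout curve.
#' @slot sizeFactorSdLog sdlog of the log-normal per-cell size factors.
#' @slot bmSigma2 Brownian-motion variance rate per unit branch length.
#' @slot rootState numeric vector of trait values at the root.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nTaxaPerClade = "integer",
  nSites = "integer",
  propType2 = "numeric",
  withinCladeSubRate = "numeric",
  nCellsPerType = "integer",
  nbSize = "numeric",
  dropoutLambda = "numeric",
  dropoutMidpoint = "numeric",
  dropoutSlope = "numeric",
  sizeFactorSdLog = "numeric",
  bmSigma2 = "numeric",
  rootState = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@propType2) != 1 || is.na(object@propType2) ||
      object@propType2 < 0 || object@propType2 > 1)
    msg <- c(msg, "propType2 must be a single value in [0, 1]")
  if (object@withinCladeSubRate < 0 || object@withinCladeSubRate >= 1)
    msg <- c(msg, "withinCladeSubRate must lie in [0, 1)")
  if (object@nbSize <= 0) msg <- c(msg, "nbSize must be > 0")
  if (object@dropoutLambda <= 0) msg <- c(msg, "dropoutLambda must be > 0")
  if (object@dropoutSlope <= 0) msg <- c(msg, "dropoutSlope must be > 0")
  if (object@sizeFactorSdLog < 0) msg <- c(msg, "sizeFactorSdLog must be >= 0")
  if (object@bmSigma2 < 0) msg <- c(msg, "bmSigma2 must be >= 0")
  if (object@nSites < 1) msg <- c(msg, "nSites must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Clade-labelled amino-acid alignment
#'
#' An aligned set of equal-length amino-acid sequences (20-letter alphabet
#' plus gap \code{-} and missing \code{X}) together with a taxon-to-clade map.
#'
#' @slot sequences an [Biostrings::AAStringSet] of equal-length sequences.
#' @slot cladeOf named character; clade label per taxon.
#' @slot type2Sites integer vector of ground-truth divergent site indices
#'   (empty for real data; populated by [simulateCladeAlignment()]).
#' @export
setClass("CladeAlignment", representation(
  sequences = "AAStringSet",
  cladeOf = "character",
  type2Sites = "integer"
))

setValidity("CladeAlignment", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (n < 1) msg <- c(msg, "alignment must contain at least one sequence")
  w <- Biostrings::width(object@sequences)
  if (n >= 1 && length(unique(w)) > 1)
    msg <- c(msg, "all sequences must have equal length")
  taxa <- names(object@sequences)
  if (is.null(taxa) || anyDuplicated(taxa))
    msg <- c(msg, "sequences must carry unique taxon names")
  if (!all(taxa %in% names(object@cladeOf)))
    msg <- c(msg, "cladeOf must label every taxon")
  if (length(msg)) msg else TRUE
})

#' Pairwise percent sequence identity matrix
#'
#' @slot values symmetric numeric matrix of pairwise %seqID in [0, 100];
#'   \code{NA} marks pairs with no comparable columns.
#' @slot deletionMode \code{"pairwise"} or \code{"complete"}.
#' @export
setClass("SeqIdentityMatrix", representation(
  values = "matrix",
  deletionMode = "character"
))

setValidity("SeqIdentityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!isSymmetric(unname(v))) msg <- c(msg, "matrix must be symmetric")
  if (any(!is.na(v) & (v < 0 | v > 100)))
    msg <- c(msg, "identities must lie in [0, 100]")
  if (any(diag(v) != 100)) msg <- c(msg, "diagonal must equal 100")
  if (!object@deletionMode %in% c("pairwise", "complete"))
    msg <- c(msg, "deletionMode must be 'pairwise' or 'complete'")
  if (length(msg)) msg else TRUE
})

#' Type-II functional divergence result
#'
#' Estimate of the type-II divergence coefficient between two clades, its
#' uncertainty, and per-site posterior probabilities of divergence.
#'
#' @slot theta2 estimated coefficient in [0, 1].
#' @slot se standard error of the estimate.
#' @slot z z-score against the null theta2 = 0.
#' @slot pValue one-sided p-value.
#' @slot sitePosteriors per-site posterior probability of type-II divergence
#'   (\code{NA} for sites excluded by the coverage filter).
#' @slot sitePatterns per-site category: \code{candidate},
#'   \code{conserved_same_residue}, \code{conserved_same_group},
#'   \code{variable}, or \code{excluded}.
#' @slot nSitesUsed number of classifiable sites entering the mixture.
#' @export
setClass("TypeIIDivergence", representation(
  theta2 = "numeric",
  se = "numeric",
  z = "numeric",
  pValue = "numeric",
  sitePosteriors = "numeric",
  sitePatterns = "character",
  nSitesUsed = "integer"
))

setValidity("TypeIIDivergence", function(object) {
  msg <- character()
  if (object@theta2 < 0 || object@theta2 > 1)
    msg <- c(msg, "theta2 must lie in [0, 1]")
  p <- object@sitePosteriors
  if (any(!is.na(p) & (p < 0 | p > 1)))
    msg <- c(msg, "site posteriors must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Single-cell expression error model
#'
#' Weighted mixture of a negative binomial (detected transcripts) and a
#' low-magnitude Poisson (dropout). Dropout probability is a decreasing
#' logistic in log10 expression. The curve and NB size are fitted jointly for
#' a cell type; per-cell rows are kept so downstream code can address cells
#' individually.
#'
#' @slot dropoutMidpoint per-cell log10 expression at 50% dropout.
#' @slot dropoutSlope per-cell logistic slope.
#' @slot nbSize shared NB size r.
#' @slot dropoutLambda Poisson mean of the dropout component.
#' @slot converged logical convergence flag of the EM fit.
#' @slot nIter EM iterations used.
#' @export
setClass("ExpressionErrorModel", representation(
  dropoutMidpoint = "numeric",
  dropoutSlope = "numeric",
  nbSize = "numeric",
  dropoutLambda = "numeric",
  converged = "logical",
  nIter = "integer"
))

setValidity("ExpressionErrorModel", function(object) {
  msg <- character()
  if (object@nbSize <= 0) msg <- c(msg, "nbSize must be > 0")
  if (object@dropoutLambda <= 0) msg <- c(msg, "dropoutLambda must be > 0")
  if (any(object@dropoutSlope <= 0))
    msg <- c(msg, "dropoutSlope must be > 0 (dropout non-increasing in expression)")
  if (length(msg)) msg else TRUE
})

#' Posterior over mean expression per gene in one cell type
#'
#' @slot cellType the cell type the posterior refers to.
#' @slot grid strictly increasing grid of mean expression values (linear
#'   scale, log10-spaced).
#' @slot weights genes x grid matrix of normalized posterior weights.
#' @slot posteriorMean per-gene posterior mean expression.
#' @export
setClass("ExpressionPosterior", representation(
  cellType = "character",
  grid = "numeric",
  weights = "matrix",
  posteriorMean = "numeric"
))

setValidity("ExpressionPosterior", function(object) {
  msg <- character()
  if (any(diff(object@grid) <= 0)) msg <- c(msg, "grid must be strictly increasing")
  s <- rowSums(object@weights)
  if (any(abs(s - 1) > 1e-9)) msg <- c(msg, "posterior weights must sum to 1 per gene")
  if (length(msg)) msg else TRUE
})

#' Catalog of validated pentameric receptor assemblies
#'
#' Each assembly names the multiset of subunit genes filling its five slots
#' (e.g. two alpha9 plus three alpha10 copies).
#'
#' @slot assemblies named list; each element a named integer vector of copy
#'   numbers per subunit gene, summing to 5 over 1-4 distinct genes.
#' @export
setClass("PentamerCatalog", representation(assemblies = "list"))

setValidity("PentamerCatalog", function(object) {
  msg <- character()
  if (!length(object@assemblies)) msg <- c(msg, "catalog must not be empty")
  for (nm in names(object@assemblies)) {
    a <- object@assemblies[[nm]]
    if (sum(a) != 5)
      msg <- c(msg, sprintf("assembly '%s' must have 5 subunit slots", nm))
    if (length(a) < 1 || length(a) > 4)
      msg <- c(msg, sprintf("assembly '%s' must use 1-4 distinct genes", nm))
    if (any(a < 1)) msg <- c(msg, sprintf("assembly '%s' has non-positive copies", nm))
  }
  if (length(msg)) msg else TRUE
})

#' PCA model of max-normalized functional profiles
#'
#' @slot normConstants per-property maxima used for normalization.
#' @slot centers per-property column means after normalization.
#' @slot loadings property x PC orthonormal loading matrix.
#' @slot scores receptor x PC score matrix.
#' @slot varianceFractions fraction of total variance per PC (sums to 1).
#' @slot scale \code{"covariance"} or \code{"correlation"}.
#' @slot scaleSd per-property standard deviations divided out under
#'   correlation scaling (all 1 under covariance scaling).
#' @export
setClass("PCAModel", representation(
  normConstants = "numeric",
  centers = "numeric",
  loadings = "matrix",
  scores = "matrix",
  varianceFractions = "numeric",
  scale = "character",
  scaleSd = "numeric"
))

setValidity("PCAModel", function(object) {
  msg <- character()
  if (abs(sum(object@varianceFractions) - 1) > 1e-9)
    msg <- c(msg, "variance fractions must sum to 1")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(ncol(g)))) > 1e-8)
    msg <- c(msg, "loadings must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' Brownian-motion ancestral trait estimates
#'
#' @slot estimates internal node x trait matrix of ML ancestral states.
#' @slot ci95Lower,ci95Upper matching 95% confidence bounds.
#' @slot sigma2 per-trait ML estimate of the BM rate.
#' @slot rootOnly logical; TRUE when only the root was estimated.
#' @export
setClass("AncestralTraits", representation(
  estimates = "matrix",
  ci95Lower = "matrix",
  ci95Upper = "matrix",
  sigma2 = "numeric",
  rootOnly = "logical"
))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed,
      "| taxa/clade", object@nTaxaPerClade,
      "| sites", object@nSites,
      "| propType2", object@propType2,
      "| sub rate", object@withinCladeSubRate, "\n")
  cat("  counts: cells/type", object@nCellsPerType,
      "NB size", object@nbSize,
      "dropout(mid,slope,lambda)",
      paste(object@dropoutMidpoint, object@dropoutSlope, object@dropoutLambda),
      "\n")
  cat("  traits: sigma2", object@bmSigma2,
      "root", paste(signif(object@rootState, 3), collapse = ","), "\n")
})

setMethod("show", "CladeAlignment", function(object) {
  cat("CladeAlignment:", length(object@sequences), "taxa x",
      Biostrings::width(object@sequences)[1], "sites;",
      length(unique(object@cladeOf)), "clades")
  if (length(object@type2Sites))
    cat(";", length(object@type2Sites), "truth divergent sites")
  cat("\n")
})

setMethod("show", "SeqIdentityMatrix", function(object) {
  cat("SeqIdentityMatrix:", nrow(object@values), "taxa,",
      object@deletionMode, "deletion\n")
  v <- object@values[upper.tri(object@values)]
  if (length(v))
    cat("  %seqID range:", paste(signif(range(v, na.rm = TRUE), 4),
                                 collapse = " - "), "\n")
})

setMethod("show", "TypeIIDivergence", function(object) {
  cat(sprintf("TypeIIDivergence: theta2 = %.4f (SE %.4f), z = %.2f, p = %.3g\n",
              object@theta2, object@se, object@z, object@pValue))
  cat("  sites used:", object@nSitesUsed,
      "| candidates:", sum(object@sitePatterns == "candidate"), "\n")
})

setMethod("show", "ExpressionErrorModel", function(object) {
  cat(sprintf(
    "ExpressionErrorModel: %d cells | NB size %.3f | dropout mid %.3f slope %.3f lambda %.3f | %s (%d iter)\n",
    length(object@dropoutMidpoint), object@nbSize, object@dropoutMidpoint[1],
    object@dropoutSlope[1], object@dropoutLambda,
    if (object@converged) "converged" else "NOT converged", object@nIter))
})

setMethod("show", "ExpressionPosterior", function(object) {
  cat("ExpressionPosterior:", nrow(object@weights), "genes,",
      length(object@grid), "grid points, cell type", object@cellType, "\n")
})

setMethod("show", "PentamerCatalog", function(object) {
  cat("PentamerCatalog:", length(object@assemblies), "assemblies:",
      paste(utils::head(names(object@assemblies), 8), collapse = ", "),
      if (length(object@assemblies) > 8) "..." else "", "\n")
})

setMethod("show", "PCAModel", function(object) {
  cat("PCAModel (", object@scale, "): ", nrow(object@scores), " observations x ",
      nrow(object@loadings), " properties\n", sep = "")
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_along(object@varianceFractions),
                    100 * object@varianceFractions), collapse = ", "), "\n")
})

setMethod("show", "AncestralTraits", function(object) {
  cat("AncestralTraits:", nrow(object@estimates), "nodes x",
      ncol(object@estimates), "traits; sigma2 =",
      paste(signif(object@sigma2, 4), collapse = ", "), "\n")
})
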