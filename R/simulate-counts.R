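#' Simulate single-cell counts under an NB + dropout-Poisson mixture
#'
#' Per cell and gene, with probability given by a decreasing logistic in
#' log10 mean expression (midpoint \code{dropoutMidpoint}, slope
#' \code{dropoutSlope}), the observation is a dropout and a low-magnitude
#' Poisson (\code{dropoutLambda}) count is drawn; otherwise a negative
#' binomial with mean \code{m * s_c} and size \code{nbSize}, where the
#' per-cell size factor \code{s_c} is log-normal(0, sizeFactorSdLog).
#'
#' @param cfg a [SimConfig-class].
#' @param meanMatrix genes x cell-types matrix of true mean expression
#'   (finite, >= 0), with row and column names.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assays
#'   \code{counts} and \code{dropout} (logical truth flags), per-cell
#'   \code{cellType} and \code{sizeFactorTruth} in \code{colData}, and the
#'   truth mean matrix in \code{metadata(.)$truthMeans}.
#' @examples
#' mm <- matrix(c(5, 50), 2, 1, dimnames = list(c("g1", "g2"), "tA"))
#' sce <- simulateCounts(SimConfig(seed = 1, nCellsPerType = 10), mm)
#' dim(sce)
#' @export
simulateCounts <- function(cfg, meanMatrix) {
  stopifnot(is(cfg, "SimConfig"), is.matrix(meanMatrix))
  if (any(!is.finite(meanMatrix)) || any(meanMatrix < 0))
    stop("meanMatrix must be finite and non-negative")
  if (is.null(rownames(meanMatrix)))
    rownames(meanMatrix) <- paste0("gene", seq_len(nrow(meanMatrix)))
  if (is.null(colnames(meanMatrix)))
    colnames(meanMatrix) <- paste0("type", seq_len(ncol(meanMatrix)))

  nGenes <- nrow(meanMatrix)
  types <- colnames(meanMatrix)
  nCells <- cfg@nCellsPerType * length(types)

  .withSimSeed(cfg, 1L, {
    cellType <- rep(types, each = cfg@nCellsPerType)
    sf <- stats::rlnorm(nCells, meanlog = 0, sdlog = cfg@sizeFactorSdLog)

    m <- meanMatrix[, cellType, drop = FALSE]              # genes x cells
    pDrop <- dropoutProbability(m, cfg@dropoutMidpoint, cfg@dropoutSlope)
    drop <- matrix(stats::runif(length(m)) < pDrop, nrow = nGenes)
    mu <- sweep(m, 2L, sf, `*`)
    counts <- matrix(0L, nGenes, nCells,
                     dimnames = list(rownames(meanMatrix),
                                     paste0("cell", seq_len(nCells))))
    counts[drop] <- stats::rpois(sum(drop), cfg@dropoutLambda)
    counts[!drop] <- stats::rnbinom(sum(!drop), mu = mu[!drop],
                                    size = cfg@nbSize)
    dimnames(drop) <- dimnames(counts)

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts, dropout = drop),
      colData = S4Vectors::DataFrame(cellType = cellType,
                                     sizeFactorTruth = sf,
                                     row.names = colnames(counts)))
    S4Vectors::metadata(sce)$truthMeans <- meanMatrix
    sce
  })
}

#' Dropout probability as a function of mean expression
#'
#' Logistic in log10 expression, decreasing: probability 1 at zero
#' expression, 0.5 at \code{midpoint}.
#'
#' @param m mean expression (linear scale), any numeric shape.
#' @param midpoint log10 expression at 50% dropout.
#' @param slope logistic slope per log10 unit (> 0).
#' @return dropout probabilities in [0, 1], same shape as \code{m}.
#' @export
dropoutProbability <- function(m, midpoint, slope) {
  if (is.infinite(midpoint)) {
    # limiting curves: midpoint -> -Inf disables dropout entirely,
    # midpoint -> +Inf forces it
    p <- m; p[] <- if (midpoint < 0) 0 else 1
    return(p)
  }
  p <- stats::plogis(-slope * (log10(pmax(m, 0)) - midpoint))
  p[m <= 0] <- 1
  p
}
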