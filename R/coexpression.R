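#' Library-size size factors
#'
#' Per-cell scaling factors: total count divided by the geometric mean of
#' totals, so the mean of log factors is zero.
#'
#' @param counts genes x cells integer matrix, or a
#'   [SingleCellExperiment::SingleCellExperiment] with a \code{counts} assay.
#' @param method only \code{"library_size"}.
#' @return numeric vector of per-cell factors; when \code{counts} is a
#'   SingleCellExperiment the object is returned with
#'   \code{sizeFactors(.)} set.
#' @examples
#' m <- matrix(c(50, 50, 200, 200), 2, dimnames = list(NULL, c("a", "b")))
#' computeSizeFactors(m)  # 0.5, 2
#' @export
computeSizeFactors <- function(counts, method = "library_size") {
  method <- match.arg(method, "library_size")
  mat <- if (is(counts, "SingleCellExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  tot <- colSums(mat)
  if (any(tot <= 0))
    stop("cells with zero total count: ",
         paste(utils::head(colnames(mat)[tot <= 0], 10), collapse = ", "))
  sf <- tot / exp(mean(log(tot)))
  names(sf) <- colnames(mat)
  if (is(counts, "SingleCellExperiment")) {
    SingleCellExperiment::sizeFactors(counts) <- sf
    return(counts)
  }
  sf
}

# E-step: posterior probability that observation k came from the dropout
# Poisson rather than the amplified NB component.
.dropoutResponsibility <- function(k, mg, sf, midpoint, slope, nbSize,
                                   lambda0) {
  pd <- dropoutProbability(mg, midpoint, slope)
  num <- pd * stats::dpois(k, lambda0)
  den <- num + (1 - pd) * stats::dnbinom(k, mu = pmax(mg * sf, 1e-12),
                                         size = nbSize)
  ifelse(den > 0, num / den, pd)
}

#' Fit the NB + dropout-Poisson expression error model by EM
#'
#' Models each count as a weighted mixture: with probability given by a
#' decreasing logistic in the log10 gene mean, a dropout Poisson
#' (\code{lambda0}); otherwise a negative binomial with mean
#' \code{m_g * s_c} and size r. The E-step assigns each observation a
#' dropout responsibility; the M-step refits the logistic curve (midpoint,
#' slope), the NB size r by maximum likelihood, and the gene means.
#' Convergence: max absolute parameter change < \code{tol} (default 1e-4)
#' or \code{maxIter} iterations, after which the last iterate is returned
#' with a warning and \code{converged = FALSE}.
#'
#' @param counts genes x cells matrix or SingleCellExperiment (one cell
#'   type; >= 20 cells and >= 50 genes).
#' @param sizeFactors per-cell factors; defaults to the truth factors in
#'   \code{colData} when present, else [computeSizeFactors()].
#' @param lambda0 dropout Poisson mean (fixed, default 0.1).
#' @param tol,maxIter EM stopping rule.
#' @return an [ExpressionErrorModel-class].
#' @export
fitErrorModel <- function(counts, sizeFactors = NULL, lambda0 = 0.1,
                          tol = 1e-4, maxIter = 100L) {
  mat <- if (is(counts, "SingleCellExperiment"))
    SummarizedExperiment::assay(counts, "counts") else counts
  if (ncol(mat) < 20) stop("need at least 20 cells to fit the error model")
  if (nrow(mat) < 50) stop("need at least 50 genes to fit the error model")
  if (is.null(sizeFactors)) {
    sizeFactors <- if (is(counts, "SingleCellExperiment") &&
                       "sizeFactorTruth" %in%
                       colnames(SummarizedExperiment::colData(counts)))
      counts$sizeFactorTruth else computeSizeFactors(mat)
  }
  sf <- rep(sizeFactors, length.out = ncol(mat))

  # initial gene means from normalized counts; NB size by method of moments
  # on overdispersed genes (ignoring dropout) as a starting point
  norm <- sweep(mat, 2L, sf, `/`)
  mg <- pmax(rowMeans(norm), 1e-4)
  vg <- apply(norm, 1L, stats::var)
  od <- vg > mg & mg > 1
  r <- if (any(od)) stats::median(mg[od]^2 / (vg[od] - mg[od])) else 1
  r <- min(max(r, 0.01), 100)
  mid <- 0; slope <- 1

  nGenes <- nrow(mat); nCells <- ncol(mat)
  k <- as.matrix(mat)
  sfm <- matrix(sf, nGenes, nCells, byrow = TRUE)
  converged <- FALSE; iter <- 0L

  for (iter in seq_len(maxIter)) {
    mgm <- matrix(mg, nGenes, nCells)
    z <- .dropoutResponsibility(k, mgm, sfm, mid, slope, r, lambda0)

    # M-step: logistic dropout curve in log10 mean
    x <- log10(mg)
    zg <- rowMeans(z)
    nll <- function(par) {
      p <- stats::plogis(-exp(par[2]) * (x - par[1]))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(zg * log(p) + (1 - zg) * log(1 - p)) * nCells
    }
    opt <- stats::optim(c(mid, log(max(slope, 1e-3))), nll,
                        method = "Nelder-Mead")
    midNew <- opt$par[1]; slopeNew <- exp(opt$par[2])

    # M-step: NB size by weighted ML over non-dropout responsibility; one
    # safeguarded Newton step on the score per iteration (ECM-style update,
    # converges to the same maximum as a full inner optimization)
    w <- 1 - z
    mu <- pmax(mgm * sfm, 1e-12)
    score <- sum(w * (digamma(k + r) - digamma(r) + log(r) + 1 -
                        log(r + mu) - (r + k) / (r + mu)))
    info <- sum(w * (trigamma(k + r) - trigamma(r) + 1 / r -
                       2 / (r + mu) + (r + k) / (r + mu)^2))
    stepR <- if (info < 0) -score / info else sign(score) * 0.1 * r
    stepR <- sign(stepR) * min(abs(stepR), 0.5 * r)
    rNew <- min(max(r + stepR, 1e-3), 1e4)

    # M-step: gene means (weighted ratio estimator; nuisance quantities,
    # not part of the convergence criterion)
    mgNew <- pmax(rowSums(w * k) / pmax(rowSums(w * sfm), 1e-12), 1e-4)

    delta <- max(abs(midNew - mid), abs(slopeNew - slope),
                 abs(log(rNew) - log(r)))
    mid <- midNew; slope <- slopeNew; r <- rNew; mg <- mgNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge within ", maxIter,
            " iterations; returning last iterate")

  new("ExpressionErrorModel",
      dropoutMidpoint = rep(mid, nCells),
      dropoutSlope = rep(slope, nCells),
      nbSize = r, dropoutLambda = lambda0,
      converged = converged, nIter = iter)
}

#' Posterior distribution of mean expression per gene in a cell type
#'
#' On a uniform-in-log10 grid, the posterior for gene g is proportional to
#' the product over cells of the mixture likelihood
#' \code{p_drop(m) Pois(k; lambda0) + (1 - p_drop(m)) NB(k; m s_c, r)}
#' under a uniform-in-log prior, normalized over the grid.
#'
#' @param counts genes x cells matrix or SingleCellExperiment.
#' @param model an [ExpressionErrorModel-class].
#' @param cellType when \code{counts} is a SingleCellExperiment with a
#'   \code{cellType} column, restrict to these cells; otherwise all columns
#'   are used.
#' @param sizeFactors per-cell factors (defaults as in [fitErrorModel()]).
#' @param grid expression grid (linear scale); default 400 log10-spaced
#'   points from 1e-2 to 1e4.
#' @return an [ExpressionPosterior-class].
#' @export
posteriorExpression <- function(counts, model, cellType = NULL,
                                sizeFactors = NULL,
                                grid = 10^seq(-2, 4, length.out = 400)) {
  isSCE <- is(counts, "SingleCellExperiment")
  mat <- if (isSCE) SummarizedExperiment::assay(counts, "counts") else counts
  keep <- seq_len(ncol(mat))
  if (!is.null(cellType)) {
    if (!isSCE || !"cellType" %in% colnames(SummarizedExperiment::colData(counts)))
      stop("cellType selection requires a SingleCellExperiment with a cellType column")
    keep <- which(counts$cellType == cellType)
    if (!length(keep)) stop("no cells of type '", cellType, "'")
  }
  if (is.null(sizeFactors)) {
    sizeFactors <- if (isSCE && "sizeFactorTruth" %in%
                       colnames(SummarizedExperiment::colData(counts)))
      counts$sizeFactorTruth else computeSizeFactors(mat)
  }
  sf <- rep(sizeFactors, length.out = ncol(mat))[keep]
  k <- as.matrix(mat[, keep, drop = FALSE])
  nGenes <- nrow(k); nCells <- ncol(k); nGrid <- length(grid)

  pd <- dropoutProbability(grid, model@dropoutMidpoint[1], model@dropoutSlope[1])
  lw <- matrix(0, nGenes, nGrid)
  dDrop <- stats::dpois(k, model@dropoutLambda)       # genes x cells
  for (gpt in seq_len(nGrid)) {
    mu <- grid[gpt] * sf
    dAmp <- stats::dnbinom(k, mu = matrix(mu, nGenes, nCells, byrow = TRUE),
                           size = model@nbSize)
    mix <- pd[gpt] * dDrop + (1 - pd[gpt]) * dAmp
    lw[, gpt] <- rowSums(log(pmax(mix, 1e-300)))
  }
  lw <- lw - apply(lw, 1L, max)
  w <- exp(lw)
  w <- w / rowSums(w)
  pm <- as.vector(w %*% grid)
  rownames(w) <- rownames(mat)
  names(pm) <- rownames(mat)

  new("ExpressionPosterior",
      cellType = if (is.null(cellType)) "all" else cellType,
      grid = grid, weights = w, posteriorMean = pm)
}
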