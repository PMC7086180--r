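#' Brownian-motion ancestral trait estimation
#'
#' Maximum-likelihood ancestral states for continuous traits under Brownian
#' motion. The root state is the GLS estimate under the phylogenetic
#' covariance C (C_ij = shared path length from the root), the BM rate
#' sigma2 is its ML estimate, and every internal node takes the conditional
#' Gaussian expectation given the tips; 95% CIs come from the conditional
#' variances at the estimated sigma2.
#'
#' Estimates are convex combinations of tip values, so each ancestral state
#' lies within the range of its tips, and the root estimate is invariant to
#' tip ordering.
#'
#' @param tree rooted [ape::phylo] with branch lengths > 0 (a concatemer
#'   tree or any trait tree).
#' @param tipTraits named numeric vector, or tips x traits matrix with
#'   rownames matching tip labels.
#' @param reml divide the rate sum of squares by n - 1 instead of n
#'   (restricted-likelihood correction; default FALSE, plain ML).
#' @return an [AncestralTraits-class] with one row per internal node (root
#'   first, ape node order).
#' @examples
#' tr <- ape::read.tree(text = "(a:1,b:1,c:1);")
#' ancestralEstimates(bmAncestral(tr, c(a = 1, b = 2, c = 3)))  # root = 2
#' @export
bmAncestral <- function(tree, tipTraits, reml = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(dim(tipTraits)))
    tipTraits <- matrix(tipTraits, ncol = 1,
                        dimnames = list(names(tipTraits), "trait"))
  if (!all(tree$tip.label %in% rownames(tipTraits)))
    stop("all tips need trait values; missing: ",
         paste(setdiff(tree$tip.label, rownames(tipTraits)), collapse = ", "))
  y <- tipTraits[tree$tip.label, , drop = FALSE]
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")

  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  root <- nTip + 1L

  # node depths and full node-node covariance (shared path length to root)
  D <- ape::dist.nodes(tree)
  depth <- D[root, ]
  allN <- seq_len(nTip + nNode)
  Cfull <- outer(depth, depth, `+`) - D
  Cfull <- Cfull[allN, allN] / 2

  Ctt <- Cfull[seq_len(nTip), seq_len(nTip), drop = FALSE]
  Cit <- Cfull[(nTip + 1L):(nTip + nNode), seq_len(nTip), drop = FALSE]
  Cii <- Cfull[(nTip + 1L):(nTip + nNode), (nTip + 1L):(nTip + nNode),
               drop = FALSE]

  Cinv <- tryCatch(solve(Ctt), error = function(e)
    stop("singular phylogenetic covariance (e.g. a zero-length terminal ",
         "pair with conflicting tip values): ", conditionMessage(e)))

  one <- rep(1, nTip)
  denom <- as.numeric(crossprod(one, Cinv %*% one))
  nTrait <- ncol(y)
  est <- matrix(NA_real_, nNode, nTrait)
  lo <- hi <- est
  sigma2 <- numeric(nTrait)
  # conditional variance of internal states given tips, including the
  # uncertainty of the GLS root estimate (kriging variance with fitted mean)
  h <- 1 - as.vector(Cit %*% Cinv %*% one)
  condShape <- pmax(diag(Cii - Cit %*% Cinv %*% t(Cit)) + h^2 / denom, 0)
  for (j in seq_len(nTrait)) {
    yj <- y[, j]
    a <- as.numeric(crossprod(one, Cinv %*% yj)) / denom
    resid <- yj - a
    sigma2[j] <- as.numeric(crossprod(resid, Cinv %*% resid)) /
      (if (reml) nTip - 1L else nTip)
    est[, j] <- a + Cit %*% Cinv %*% resid
    condVar <- sigma2[j] * condShape
    lo[, j] <- est[, j] - 1.96 * sqrt(condVar)
    hi[, j] <- est[, j] + 1.96 * sqrt(condVar)
  }
  nodeLab <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", (nTip + 1L):(nTip + nNode))
  dimnames(est) <- dimnames(lo) <- dimnames(hi) <-
    list(nodeLab, colnames(y))
  names(sigma2) <- colnames(y)
  new("AncestralTraits", estimates = est, ci95Lower = lo, ci95Upper = hi,
      sigma2 = sigma2, rootOnly = FALSE)
}
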