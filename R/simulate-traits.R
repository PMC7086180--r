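#' Simulate continuous traits by Brownian motion on a tree
#'
#' The root takes \code{rootState}; every child node equals its parent plus
#' an independent Normal(0, sigma2 * branch length) increment per trait.
#' Internal-node values are returned so recovery of ancestral states can be
#' tested against the truth.
#'
#' @param tree an [ape::phylo] with finite branch lengths >= 0.
#' @param cfg a [SimConfig-class]; \code{bmSigma2} and \code{rootState} are
#'   the BM rate and the root trait vector.
#' @return numeric matrix (tips then internal nodes, in ape node order) x
#'   traits, with tip labels / \code{node<N>} rownames.
#' @examples
#' tr <- ape::read.tree(text = "((rat:1,chick:1):1,frog:2);")
#' x <- simulateBMTraits(tr, SimConfig(seed = 1, bmSigma2 = 1, rootState = 0))
#' @export
simulateBMTraits <- function(tree, cfg) {
  stopifnot(inherits(tree, "phylo"), is(cfg, "SimConfig"))
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree must have finite branch lengths")
  if (any(tree$edge.length < 0))
    stop("invalid input: negative branch length")
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  nTraits <- length(cfg@rootState)
  root <- nTip + 1L

  .withSimSeed(cfg, 2L, {
    x <- matrix(NA_real_, nTip + nNode, nTraits)
    x[root, ] <- cfg@rootState
    # preorder: parents before children
    ord <- rev(ape::postorder(tree))
    for (e in ord) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      sd <- sqrt(cfg@bmSigma2 * tree$edge.length[e])
      x[ch, ] <- x[p, ] + stats::rnorm(nTraits, 0, sd)
    }
    nodeLab <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
      tree$node.label else paste0("node", root:(nTip + nNode))
    rownames(x) <- c(tree$tip.label, nodeLab)
    colnames(x) <- if (nTraits == 1) "trait" else paste0("trait", seq_len(nTraits))
    x
  })
}
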