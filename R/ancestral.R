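#' @importFrom utils getFromNamespace
NULL

# Amino-acid substitution models. Both are scaled to one expected
# substitution per site per unit branch length.
#  - poisson: equal exchangeabilities, uniform stationary frequencies
#    (P_ij(t) = pi_j + (delta_ij - pi_j) exp(-beta t), beta = 20/19).
#  - jtt: JTT exchangeabilities and stationary frequencies (taken from
#    phangorn's model tables, reordered to the package alphabet).
.aaModel <- local({
  cache <- list()
  function(model = c("poisson", "jtt")) {
    model <- match.arg(model)
    if (!is.null(cache[[model]])) return(cache[[model]])
    n <- length(AA_ALPHABET20)
    if (model == "poisson") {
      bf <- rep(1 / n, n)
      Q <- matrix(1, n, n)
    } else {
      getAA <- getFromNamespace("getModelAA", "phangorn")
      env <- environment()
      getAA("JTT", bf = TRUE, Q = TRUE)   # assigns Q (lower tri) and bf here
      phOrder <- toupper(c("a", "r", "n", "d", "c", "q", "e", "g", "h", "i",
                           "l", "k", "m", "f", "p", "s", "t", "w", "y", "v"))
      S <- matrix(0, n, n, dimnames = list(phOrder, phOrder))
      S[lower.tri(S)] <- Q
      S <- S + t(S)
      perm <- match(AA_ALPHABET20, phOrder)
      Q <- S[perm, perm]
      bf <- unname(bf[perm])
    }
    Qm <- Q * rep(bf, each = n)          # Q_ij = s_ij * pi_j
    diag(Qm) <- 0
    diag(Qm) <- -rowSums(Qm)
    rate <- -sum(bf * diag(Qm))
    Qm <- Qm / rate
    # symmetrize in the pi^(1/2) basis for a stable eigendecomposition
    sq <- sqrt(bf)
    B <- diag(sq) %*% Qm %*% diag(1 / sq)
    eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
    out <- list(bf = bf, values = eig$values,
                U = diag(1 / sq) %*% eig$vectors,
                Uinv = t(eig$vectors) %*% diag(sq))
    cache[[model]] <<- out
    out
  }
})

# Transition probability matrix P(t); rows = start state, cols = end state.
.transitionMatrix <- function(t, mod) {
  P <- mod$U %*% (exp(mod$values * t) * mod$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Marginal maximum-likelihood ancestral sequence reconstruction
#'
#' Computes, per site, the marginal posterior distribution over amino acids
#' at every internal node of a tree by the pruning algorithm (a postorder
#' conditional-likelihood pass followed by a preorder pass propagating the
#' evidence from the rest of the tree). The reported ancestral sequence is
#' the per-site argmax state; ties break by fixed alphabet order. Gap and
#' \code{X} tip characters are treated as missing (all-ones likelihood).
#'
#' @param aln a [CladeAlignment-class] (or AAStringSet) covering all tree
#'   tips.
#' @param tree an [ape::phylo]; interpreted as rooted at its root node. At
#'   least one positive branch length is required.
#' @param model \code{"poisson"} (default) or \code{"jtt"}.
#' @param gammaAlpha optional shape for discrete-gamma (4 category) rate
#'   variation among sites; \code{NULL} (default) for uniform rates.
#' @return list with \code{states} (internal node x site character matrix),
#'   \code{posteriors} (list per internal node of site x 20 posterior
#'   matrices, rows summing to 1), \code{siteLogLik} (per-site marginal
#'   log-likelihood) and \code{tree}.
#' @export
ancestralSequencesML <- function(aln, tree, model = c("poisson", "jtt"),
                                 gammaAlpha = NULL) {
  model <- match.arg(model)
  mod <- .aaModel(model)
  m <- .alnMatrix(aln)
  if (!all(tree$tip.label %in% rownames(m)))
    stop("tree leaves missing from the alignment: ",
         paste(setdiff(tree$tip.label, rownames(m)), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (all(tree$edge.length <= 0) && nrow(m) > 1 &&
      !all(apply(m[tree$tip.label, , drop = FALSE], 2,
                 function(col) length(unique(col[!(col %in% c("-", "X"))])) <= 1)))
    stop("zero-length tree with conflicting tip states: ancestral states undefined")

  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  nSites <- ncol(m)
  nState <- length(AA_ALPHABET20)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(root) != 1) stop("tree must have a single root node")

  rates <- 1
  rateW <- 1
  if (!is.null(gammaAlpha)) {
    rates <- phangorn::discrete.gamma(gammaAlpha, k = 4)
    rateW <- rep(1 / 4, 4)
  }

  postorder <- ape::postorder(tree)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])

  # tip conditional likelihoods (shared across rate categories)
  tipL <- vector("list", nTip)
  for (i in seq_len(nTip)) {
    chars <- m[tree$tip.label[i], ]
    L <- matrix(0, nSites, nState)
    idx <- match(chars, AA_ALPHABET20)
    miss <- is.na(idx)
    L[cbind(which(!miss), idx[!miss])] <- 1
    L[miss, ] <- 1
    tipL[[i]] <- L
  }

  nodesInt <- (nTip + 1L):(nTip + nNode)
  postAcc <- lapply(nodesInt, function(i) matrix(0, nSites, nState))
  names(postAcc) <- as.character(nodesInt)
  siteLik <- rep(0, nSites)

  for (rc in seq_along(rates)) {
    Pedge <- lapply(seq_len(nrow(tree$edge)), function(e)
      .transitionMatrix(tree$edge.length[e] * rates[rc], mod))

    # postorder: conditional likelihoods L[v] (sites x states), scaled
    L <- vector("list", nTip + nNode)
    scaleLog <- rep(0, nSites)
    for (i in seq_len(nTip)) L[[i]] <- tipL[[i]]
    for (e in postorder) {
      v <- tree$edge[e, 1L]
      if (!is.null(L[[v]]) && v > nTip) next  # node handled when first seen
      L[[v]] <- matrix(1, nSites, nState)
      for (ce in children[[as.character(v)]]) {
        ch <- tree$edge[ce, 2L]
        L[[v]] <- L[[v]] * tcrossprod(L[[ch]], Pedge[[ce]])
      }
      mx <- pmax(apply(L[[v]], 1L, max), .Machine$double.xmin)
      L[[v]] <- L[[v]] / mx
      scaleLog <- scaleLog + log(mx)
    }

    lik <- as.vector(L[[root]] %*% mod$bf)    # scaled site likelihood
    # preorder: U[v] = evidence from the rest of the tree, in v's state space
    U <- vector("list", nTip + nNode)
    U[[root]] <- matrix(mod$bf, nSites, nState, byrow = TRUE)
    for (e in rev(postorder)) {
      v <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      A <- U[[v]]
      for (se in children[[as.character(v)]]) {
        sib <- tree$edge[se, 2L]
        if (sib == ch) next
        A <- A * tcrossprod(L[[sib]], Pedge[[se]])
      }
      U[[ch]] <- A %*% Pedge[[e]]
    }

    w <- rateW[rc] * exp(scaleLog)
    siteLik <- siteLik + w * lik
    for (v in nodesInt) {
      joint <- L[[v]] * U[[v]]              # same scaling as lik
      postAcc[[as.character(v)]] <- postAcc[[as.character(v)]] + w * joint
    }
  }

  if (any(siteLik <= 0))
    stop("zero site likelihood (conflicting tips across zero-length branches) at site(s) ",
         paste(utils::head(which(siteLik <= 0), 5), collapse = ", "))

  nodeLab <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", nodesInt)
  posteriors <- vector("list", nNode)
  states <- matrix(NA_character_, nNode, nSites,
                   dimnames = list(nodeLab, NULL))
  for (k in seq_len(nNode)) {
    P <- postAcc[[k]]
    P <- P / rowSums(P)
    colnames(P) <- AA_ALPHABET20
    posteriors[[k]] <- P
    states[k, ] <- AA_ALPHABET20[max.col(P, ties.method = "first")]
  }
  names(posteriors) <- nodeLab

  list(states = states, posteriors = posteriors,
       siteLogLik = log(siteLik), tree = tree)
}
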