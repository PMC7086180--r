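#' Type-II functional divergence between two clades
#'
#' Scans an alignment for sites conserved within each of two clades but in a
#' different biochemical property group between them (radical cluster
#' shifts), and estimates the fraction of sites showing such divergence
#' together with per-site posterior probabilities.
#'
#' Per site, the ancestral residue posterior of each clade is obtained by
#' marginal ML reconstruction ([ancestralSequencesML()]) at the root of the
#' clade subtree. A site is a \emph{candidate} when both clades are
#' conserved (all informative residues in one property group) and the
#' clade-ancestral groups differ; \emph{conserved-agreeing} sites split into
#' identical-residue and same-group/different-residue records; all others
#' are \emph{variable}. Sites with overall coverage below \code{coverage} or
#' fewer than 2 informative residues in either clade are excluded.
#'
#' The estimator is a two-component mixture over classifiable sites: a
#' type-II site shows the candidate pattern with probability 1 (its defining
#' property); a background site shows it with probability pi0, the
#' probability of a cross-group ancestral difference under the Poisson
#' substitution model at the neutral between-clade path length. That path
#' length is calibrated from the same-group/different-residue sites, which
#' cannot be type-II and measure neutral between-clade substitutions
#' directly; under the uniform-target Poisson model the expected ratio of
#' cross-group to within-group ancestral differences depends only on the
#' property partition. The ML estimate is then
#' theta2 = (f_candidate - r * f_samegroup) clipped to [0, 1], with its
#' standard error from the multinomial information, z = theta2/SE and a
#' one-sided p-value against theta2 = 0.
#'
#' @param aln a [CladeAlignment-class].
#' @param cladeA,cladeB clade labels present in \code{cladeOf(aln)}, each
#'   with >= 2 taxa.
#' @param tree [ape::phylo] over (at least) the taxa of both clades, used
#'   for the clade-subtree ancestral reconstructions. \code{NULL} builds a
#'   neighbor-joining tree from pairwise identities.
#' @param propertyGroups residue property partition (default: acidic, basic,
#'   polar, hydrophobic).
#' @param coverage minimum fraction of informative residues per site
#'   (default 0.95); lower-coverage sites are excluded.
#' @param model substitution model for ancestral reconstruction.
#' @return a [TypeIIDivergence-class].
#' @examples
#' aln <- simulateCladeAlignment(SimConfig(seed = 7, nSites = 300,
#'                                         propType2 = 0.2))
#' res <- type2Divergence(aln, "mammal", "sauropsid")
#' theta2(res)
#' @export
type2Divergence <- function(aln, cladeA, cladeB, tree = NULL,
                            propertyGroups = DEFAULT_PROPERTY_GROUPS,
                            coverage = 0.95,
                            model = c("poisson", "jtt")) {
  stopifnot(is(aln, "CladeAlignment"))
  model <- match.arg(model)
  cl <- aln@cladeOf
  taxaA <- names(cl)[cl == cladeA]
  taxaB <- names(cl)[cl == cladeB]
  if (length(taxaA) < 2 || length(taxaB) < 2)
    stop("both clades need at least 2 taxa")

  m <- .alnMatrix(aln)
  mA <- m[taxaA, , drop = FALSE]
  mB <- m[taxaB, , drop = FALSE]
  nSites <- ncol(m)

  groupOf <- rep(NA_integer_, 26)
  names(groupOf) <- LETTERS
  for (g in seq_along(propertyGroups)) groupOf[propertyGroups[[g]]] <- g

  infA <- !(mA == "-" | mA == "X")
  infB <- !(mB == "-" | mB == "X")
  cov <- (colSums(infA) + colSums(infB)) / (nrow(mA) + nrow(mB))
  usable <- cov >= coverage & colSums(infA) >= 2 & colSums(infB) >= 2

  consGroup <- function(mm, inf) {
    # per site: the single property group of a within-conserved clade, NA if
    # polymorphic across groups
    vapply(seq_len(ncol(mm)), function(s) {
      res <- mm[inf[, s], s]
      g <- unique(groupOf[res])
      if (length(g) == 1 && !is.na(g)) g else NA_integer_
    }, integer(1))
  }
  gA <- consGroup(mA, infA)
  gB <- consGroup(mB, infB)

  patterns <- rep("excluded", nSites)
  conserved <- usable & !is.na(gA) & !is.na(gB)
  patterns[usable & (is.na(gA) | is.na(gB))] <- "variable"

  if (!any(conserved)) {
    if (!any(usable)) stop("no classifiable site (coverage filter removed all)")
    stop("no site is conserved within both clades; theta2 is undefined")
  }

  # clade-ancestral residue posteriors at the clade subtree roots
  if (is.null(tree))
    tree <- distanceTree(pairwiseIdentity(aln), correction = "poisson")
  ancA <- .cladeRootPosterior(m, tree, taxaA, model)
  ancB <- .cladeRootPosterior(m, tree, taxaB, model)

  nGroups <- length(propertyGroups)
  Gmat <- matrix(0, length(AA_ALPHABET20), nGroups)
  Gmat[cbind(seq_along(AA_ALPHABET20), groupOf[AA_ALPHABET20])] <- 1
  grpA <- ancA %*% Gmat     # sites x groups
  grpB <- ancB %*% Gmat
  pCross <- 1 - rowSums(grpA * grpB)
  argA <- max.col(ancA, ties.method = "first")
  argB <- max.col(ancB, ties.method = "first")
  gArootDiff <- groupOf[AA_ALPHABET20[argA]] != groupOf[AA_ALPHABET20[argB]]

  cand <- conserved & gArootDiff
  agree <- conserved & !gArootDiff
  sameRes <- agree & (argA == argB)
  sameGrp <- agree & (argA != argB)
  patterns[cand] <- "candidate"
  patterns[sameRes] <- "conserved_same_residue"
  patterns[sameGrp] <- "conserved_same_group"

  N <- sum(usable)
  nC <- sum(cand)
  nSG <- sum(sameGrp)
  fC <- nC / N
  fSG <- nSG / N

  # expected cross-group : within-group(different residue) ancestral
  # difference ratio for one neutral substitution, uniform target residue
  sizes <- lengths(propertyGroups)
  pCrossSub <- sum(sizes * (20 - sizes)) / (20 * 19)
  pSameSub <- sum(sizes * (sizes - 1)) / (20 * 19)
  r <- pCrossSub / pSameSub

  thetaRaw <- fC - r * fSG
  theta <- min(max(thetaRaw, 0), 1)
  varTheta <- (fC * (1 - fC) + r^2 * fSG * (1 - fSG) + 2 * r * fC * fSG) / N
  se <- sqrt(varTheta)
  z <- if (se > 0) theta / se else 0
  p <- stats::pnorm(z, lower.tail = FALSE)

  post <- rep(NA_real_, nSites)
  post[usable] <- 0
  if (nC > 0) {
    base <- min(max(thetaRaw * N / nC, 0), 1)  # P(type-II | candidate)
    post[cand] <- base * pCross[cand]
  }

  new("TypeIIDivergence", theta2 = theta, se = se, z = z, pValue = p,
      sitePosteriors = post, sitePatterns = patterns,
      nSitesUsed = as.integer(N))
}

# marginal posterior over residues at the root of the induced clade subtree
.cladeRootPosterior <- function(m, tree, taxa, model) {
  sub <- ape::keep.tip(tree, taxa)
  if (!ape::is.rooted(sub)) sub <- ape::root(sub, taxa[1], resolve.root = TRUE)
  seqs <- Biostrings::AAStringSet(apply(m[taxa, , drop = FALSE], 1L,
                                        paste0, collapse = ""))
  names(seqs) <- taxa
  rec <- ancestralSequencesML(seqs, sub, model = model)
  rootId <- setdiff(sub$edge[, 1L], sub$edge[, 2L])
  rec$posteriors[[rootId - length(sub$tip.label)]]
}
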