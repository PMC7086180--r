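#' Pairwise percent sequence identity
#'
#' Identity between two aligned sequences is 100 times the number of
#' matching columns over the number of comparable columns, where a column is
#' comparable when both residues are informative (not gap \code{-} and not
#' missing \code{X}). Under complete deletion, columns with a gap or missing
#' residue in \emph{any} taxon are removed before comparison; under pairwise
#' deletion columns are dropped per pair.
#'
#' @param aln a [CladeAlignment-class] (or AAStringSet).
#' @param mode \code{"pairwise"} (default) or \code{"complete"} deletion.
#' @return a [SeqIdentityMatrix-class]; pairs with zero comparable columns
#'   are flagged \code{NA} (undefined), never 0.
#' @examples
#' aln <- CladeAlignment(c(a = "ACDEF", b = "ACDFF"),
#'                       c(a = "c1", b = "c1"))
#' identityValues(pairwiseIdentity(aln))["a", "b"]  # 80
#' @export
pairwiseIdentity <- function(aln, mode = c("pairwise", "complete")) {
  mode <- match.arg(mode)
  m <- .alnMatrix(aln)
  if (nrow(m) < 1) stop("alignment is empty")
  inf <- !(m == "-" | m == "X")
  if (mode == "complete") {
    keep <- colSums(!inf) == 0
    m <- m[, keep, drop = FALSE]
    inf <- inf[, keep, drop = FALSE]
  }
  n <- nrow(m)
  v <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  diag(v) <- 100
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        comp <- inf[i, ] & inf[j, ]
        nc <- sum(comp)
        v[i, j] <- v[j, i] <-
          if (nc == 0) NA_real_ else 100 * sum(m[i, comp] == m[j, comp]) / nc
      }
    }
  }
  new("SeqIdentityMatrix", values = v, deletionMode = mode)
}

#' Mean percent identity within and between clades
#'
#' Within-clade means exclude self-pairs; between-clade means run over all
#' cross pairs. A clade of size one has no within pairs and its within mean
#' is reported as \code{NA}.
#'
#' @param mat a [SeqIdentityMatrix-class].
#' @param cladeOf named character vector (taxon -> clade), e.g.
#'   \code{cladeOf(aln)}.
#' @return data.frame with columns \code{cladeA}, \code{cladeB} (equal for
#'   within-clade rows), \code{meanIdentity}, \code{nPairs}.
#' @export
cladeAverageIdentity <- function(mat, cladeOf) {
  stopifnot(is(mat, "SeqIdentityMatrix"))
  v <- mat@values
  taxa <- rownames(v)
  if (length(taxa) < 2) stop("need at least 2 taxa")
  if (!all(taxa %in% names(cladeOf)))
    stop("cladeOf must label every taxon in the matrix")
  cl <- cladeOf[taxa]
  clades <- unique(cl)
  res <- list()
  for (i in seq_along(clades)) {
    for (j in i:length(clades)) {
      a <- taxa[cl == clades[i]]
      b <- taxa[cl == clades[j]]
      if (i == j) {
        if (length(a) < 2) {
          vals <- numeric()
        } else {
          sub <- v[a, a, drop = FALSE]
          vals <- sub[upper.tri(sub)]
        }
      } else {
        vals <- as.vector(v[a, b, drop = FALSE])
      }
      res[[length(res) + 1L]] <- data.frame(
        cladeA = clades[i], cladeB = clades[j],
        meanIdentity = if (length(vals)) mean(vals) else NA_real_,
        nPairs = length(vals))
    }
  }
  do.call(rbind, res)
}

#' Neighbor-joining distance tree from percent identities
#'
#' Converts identities to distances (\code{p}: d = 1 - seqID/100;
#' \code{poisson}: d = -ln(1 - p), a multiple-hit correction) and builds an
#' unrooted neighbor-joining tree.
#'
#' @param mat a [SeqIdentityMatrix-class], or a distance matrix /
#'   [stats::dist] already on the distance scale (then used as-is).
#' @param correction \code{"p"} (default) or \code{"poisson"}.
#' @return an unrooted [ape::phylo]; tiny negative NJ branch lengths are
#'   clamped to zero.
#' @export
distanceTree <- function(mat, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  if (is(mat, "SeqIdentityMatrix")) {
    v <- mat@values
    if (anyNA(v))
      stop("undefined pairwise identities present; rerun pairwiseIdentity ",
           "with mode = 'complete'")
    d <- 1 - v / 100
    if (correction == "poisson") {
      if (any(d[upper.tri(d)] >= 1))
        stop("p-distance of 1 cannot be Poisson-corrected")
      d <- -log(1 - d)
    }
  } else {
    d <- as.matrix(mat)
  }
  if (nrow(d) < 3) stop("need at least 3 taxa for a tree")
  if (any(!is.finite(d))) stop("distances must be finite")
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
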