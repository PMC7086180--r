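#' Concatemer tree with 1 - SeqID branch lengths
#'
#' Builds, for one receptor, the fixed five-node tetrapod tree
#' \code{((rat,chick)amniote,frog)tetrapod} whose node sequences are
#' concatemers: each node's subunit sequences repeated according to the
#' receptor stoichiometry in a fixed subunit order. Every edge length is
#' 1 minus the fractional sequence identity (pairwise deletion) between the
#' concatemers at its two endpoints, so lengths lie in [0, 1].
#'
#' @param subunitSequences named list with one element per node (tips and
#'   ancestors); each element a named character vector (or AAStringSet) of
#'   aligned subunit sequences.
#' @param stoichiometry named integer vector of copies per subunit, summing
#'   to 5 (e.g. \code{c(chrna9 = 2, chrna10 = 3)}); concatenation follows
#'   its name order.
#' @param tips,ancestors node names; ancestors are
#'   \code{c(inner, root)} for the fixed topology
#'   \code{((tip1,tip2)inner,tip3)root}.
#' @return an [ape::phylo] with node labels and 1-SeqID edge lengths; the
#'   concatemer sequences are attached as \code{attr(tree, "concatemers")}.
#' @examples
#' s <- c(chrna9 = "ACDEF", chrna10 = "GHIKL")
#' seqs <- list(rat = s, chick = s, frog = s, amniote = s, tetrapod = s)
#' tr <- concatemerTree(seqs, c(chrna9 = 2, chrna10 = 3))
#' range(tr$edge.length)  # all 0
#' @export
concatemerTree <- function(subunitSequences, stoichiometry,
                           tips = c("rat", "chick", "frog"),
                           ancestors = c("amniote", "tetrapod")) {
  nodes <- c(tips, ancestors)
  if (!all(nodes %in% names(subunitSequences)))
    stop("sequences required at all nodes: missing ",
         paste(setdiff(nodes, names(subunitSequences)), collapse = ", "))
  if (sum(stoichiometry) != 5)
    stop("stoichiometry must fill 5 pentamer slots")

  concat <- vapply(nodes, function(nd) {
    s <- subunitSequences[[nd]]
    s <- stats::setNames(as.character(s), names(s))
    if (!all(names(stoichiometry) %in% names(s)))
      stop("node '", nd, "' lacks subunit(s): ",
           paste(setdiff(names(stoichiometry), names(s)), collapse = ", "))
    paste(rep(s[names(stoichiometry)], times = stoichiometry),
          collapse = "")
  }, character(1))
  if (length(unique(nchar(concat))) != 1)
    stop("concatemer length mismatch across nodes: ",
         paste(nodes, nchar(concat), sep = "=", collapse = ", "))

  fracId <- function(a, b) {
    im <- pairwiseIdentity(CladeAlignment(c(x = unname(a), y = unname(b)),
                                          c(x = "1", y = "2")))
    identityValues(im)["x", "y"] / 100
  }
  inner <- ancestors[1]; root <- ancestors[2]
  edges <- list(c(root, inner), c(inner, tips[1]), c(inner, tips[2]),
                c(root, tips[3]))
  len <- vapply(edges, function(e) 1 - fracId(concat[e[1]], concat[e[2]]),
                numeric(1))

  txt <- sprintf("((%s:%.10f,%s:%.10f)%s:%.10f,%s:%.10f)%s;",
                 tips[1], len[2], tips[2], len[3], inner, len[1],
                 tips[3], len[4], root)
  tree <- ape::read.tree(text = txt)
  attr(tree, "concatemers") <- concat
  tree
}
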