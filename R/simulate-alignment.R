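#' Simulate a clade-structured amino-acid alignment
#'
#' Generates an alignment with the structure assumed by the type-II
#' divergence estimator: a recorded subset of sites carries a radical
#' (cross-property-group) difference between clades while being perfectly
#' conserved within each clade; all remaining sites share a common base
#' residue and accumulate independent substitutions at
#' \code{withinCladeSubRate} per taxon.
#'
#' With up to four clades, every divergent site places each clade in a
#' different biochemical property group; additional clades recycle groups.
#'
#' @param cfg a [SimConfig-class].
#' @param clades character vector of >= 2 clade labels.
#' @param propertyGroups list of residue property groups (default: acidic,
#'   basic, polar, hydrophobic).
#' @return a [CladeAlignment-class] whose \code{type2Sites} slot records the
#'   ground-truth divergent site indices.
#' @examples
#' aln <- simulateCladeAlignment(SimConfig(seed = 1, nSites = 200,
#'                                         propType2 = 0.2))
#' length(type2Sites(aln))  # 40
#' @export
simulateCladeAlignment <- function(cfg,
                                   clades = c("mammal", "sauropsid"),
                                   propertyGroups = DEFAULT_PROPERTY_GROUPS) {
  stopifnot(is(cfg, "SimConfig"))
  if (length(clades) < 2) stop("at least 2 clades are required")
  if (anyDuplicated(clades)) stop("clade labels must be unique")
  if (cfg@nTaxaPerClade < 2)
    stop("invalid input: every clade needs at least 2 taxa")
  nSites <- cfg@nSites
  nClades <- length(clades)
  nTaxa <- cfg@nTaxaPerClade * nClades

  .withSimSeed(cfg, 0L, {
    nT2 <- floor(cfg@propType2 * nSites)
    t2 <- if (nT2 > 0) sort(sample.int(nSites, nT2)) else integer()

    # background base residue per site, shared by all taxa
    base <- sample(AA_ALPHABET20, nSites, replace = TRUE)
    mat <- matrix(rep(base, each = nTaxa), nrow = nTaxa, ncol = nSites)

    # divergent sites: each clade fixed for a residue from a distinct group
    nGroups <- length(propertyGroups)
    for (s in t2) {
      ord <- sample.int(nGroups)
      for (k in seq_len(nClades)) {
        grp <- propertyGroups[[ord[((k - 1L) %% nGroups) + 1L]]]
        res <- grp[sample.int(length(grp), 1L)]
        rows <- ((k - 1L) * cfg@nTaxaPerClade + 1L):(k * cfg@nTaxaPerClade)
        mat[rows, s] <- res
      }
    }

    # independent within-clade noise at background sites only
    bg <- setdiff(seq_len(nSites), t2)
    if (length(bg) && cfg@withinCladeSubRate > 0) {
      sub <- matrix(stats::runif(nTaxa * length(bg)) < cfg@withinCladeSubRate,
                    nrow = nTaxa)
      idx <- which(sub, arr.ind = TRUE)
      if (nrow(idx)) {
        cur <- mat[cbind(idx[, 1L], bg[idx[, 2L]])]
        new <- vapply(cur, function(r) {
          sample(setdiff(AA_ALPHABET20, r), 1L)
        }, character(1))
        mat[cbind(idx[, 1L], bg[idx[, 2L]])] <- new
      }
    }

    taxa <- as.vector(vapply(clades, function(cl)
      paste0(cl, "_t", seq_len(cfg@nTaxaPerClade)), character(cfg@nTaxaPerClade)))
    seqs <- Biostrings::AAStringSet(apply(mat, 1L, paste0, collapse = ""))
    names(seqs) <- taxa
    cladeMap <- stats::setNames(rep(clades, each = cfg@nTaxaPerClade), taxa)

    new("CladeAlignment", sequences = seqs, cladeOf = cladeMap,
        type2Sites = as.integer(t2))
  })
}

#' Build a CladeAlignment from sequences and a clade map
#'
#' @param sequences an [Biostrings::AAStringSet], named character vector, or
#'   path to an aligned FASTA file.
#' @param cladeOf named character vector mapping taxon names to clade labels,
#'   or a two-column data.frame (taxon, clade), or a TSV path with those
#'   columns.
#' @return a [CladeAlignment-class].
#' @export
CladeAlignment <- function(sequences, cladeOf) {
  if (is.character(sequences) && length(sequences) == 1 && file.exists(sequences))
    sequences <- Biostrings::readAAStringSet(sequences)
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  if (is.character(cladeOf) && length(cladeOf) == 1 && file.exists(cladeOf))
    cladeOf <- utils::read.delim(cladeOf, stringsAsFactors = FALSE)
  if (is.data.frame(cladeOf))
    cladeOf <- stats::setNames(as.character(cladeOf[[2]]),
                               as.character(cladeOf[[1]]))
  new("CladeAlignment", sequences = sequences, cladeOf = cladeOf,
      type2Sites = integer())
}

# alignment as a taxa x sites character matrix
.alnMatrix <- function(aln) {
  seqs <- if (is(aln, "CladeAlignment")) aln@sequences else aln
  m <- do.call(rbind, strsplit(as.character(seqs), ""))
  rownames(m) <- names(seqs)
  m
}
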