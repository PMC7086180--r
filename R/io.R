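#' Export a clade alignment to FASTA plus sidecar tables
#'
#' Writes \code{<prefix>.fasta} (aligned sequences),
#' \code{<prefix>_clades.tsv} (taxon, clade) and, when ground-truth
#' divergent sites are recorded, \code{<prefix>_truth_sites.tsv}.
#'
#' @param aln a [CladeAlignment-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default \code{"alignment"}).
#' @return invisibly, the paths written.
#' @export
exportCladeAlignment <- function(aln, dir, prefix = "alignment") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  Biostrings::writeXStringSet(aln@sequences, fa)
  cl <- file.path(dir, paste0(prefix, "_clades.tsv"))
  utils::write.table(data.frame(taxon = names(aln@cladeOf),
                                clade = unname(aln@cladeOf)),
                     cl, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(fa, cl)
  if (length(aln@type2Sites)) {
    tr <- file.path(dir, paste0(prefix, "_truth_sites.tsv"))
    utils::write.table(data.frame(site = aln@type2Sites),
                       tr, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, tr)
  }
  invisible(paths)
}

#' Export a count experiment to MTX + sidecar tables
#'
#' Writes \code{matrix.mtx} (sparse counts), \code{genes.tsv} and
#' \code{cells.tsv} (cell, cellType, and any truth size factors).
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a
#'   \code{counts} assay and \code{cellType} column.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
exportCounts <- function(sce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(SummarizedExperiment::assay(sce, "counts"),
                      sparse = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, mtx)
  genes <- file.path(dir, "genes.tsv")
  utils::write.table(data.frame(gene = rownames(sce)), genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd <- cbind(cell = rownames(cd), cd)
  cells <- file.path(dir, "cells.tsv")
  utils::write.table(cd, cells, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mtx, genes, cells))
}

#' Import a count experiment from MTX or dense TSV
#'
#' @param countsPath \code{matrix.mtx} (with \code{genes.tsv} /
#'   \code{cells.tsv} alongside) or a dense TSV with gene rownames and cell
#'   columns.
#' @param cellsPath optional TSV of cell labels (columns \code{cell},
#'   \code{cellType}); defaults to \code{cells.tsv} next to an MTX file.
#' @return a [SingleCellExperiment::SingleCellExperiment].
#' @export
importCounts <- function(countsPath, cellsPath = NULL) {
  if (grepl("\\.mtx$", countsPath)) {
    m <- as.matrix(Matrix::readMM(countsPath))
    gdir <- dirname(countsPath)
    genes <- utils::read.delim(file.path(gdir, "genes.tsv"))
    rownames(m) <- genes[[1]]
    if (is.null(cellsPath)) cellsPath <- file.path(gdir, "cells.tsv")
  } else {
    m <- as.matrix(utils::read.delim(countsPath, row.names = 1,
                                     check.names = FALSE))
  }
  if (is.null(cellsPath) || !file.exists(cellsPath))
    stop("cell label table not found: ", cellsPath)
  cd <- utils::read.delim(cellsPath, stringsAsFactors = FALSE)
  if (!"cellType" %in% colnames(cd))
    stop("cells table needs a cellType column")
  colnames(m) <- cd$cell
  storage.mode(m) <- "integer"
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(cd[, setdiff(colnames(cd), "cell"),
                                      drop = FALSE],
                                   row.names = cd$cell))
}

#' Write a percent-identity matrix as TSV
#'
#' @param mat a [SeqIdentityMatrix-class].
#' @param path output TSV path.
#' @export
writeIdentityMatrix <- function(mat, path) {
  utils::write.table(identityValues(mat), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
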