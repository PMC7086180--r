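#' Construct a pentamer assembly catalog
#'
#' @param x named list of named integer vectors (copies per subunit gene,
#'   summing to 5), or a data.frame / TSV path with columns \code{assembly},
#'   \code{subunit}, \code{copies}.
#' @return a [PentamerCatalog-class].
#' @examples
#' cat5 <- PentamerCatalog(list(a9a10 = c(chrna9 = 2, chrna10 = 3),
#'                              a7 = c(chrna7 = 5)))
#' @export
PentamerCatalog <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
  if (is.data.frame(x)) {
    need <- c("assembly", "subunit", "copies")
    if (!all(need %in% colnames(x)))
      stop("catalog table needs columns: ", paste(need, collapse = ", "))
    x <- lapply(split(x, x$assembly), function(d)
      stats::setNames(as.integer(d$copies), d$subunit))
  }
  new("PentamerCatalog", assemblies = x)
}

#' Classify receptor-assembly coexpression by fold range
#'
#' A subunit is \emph{expressed} in a cell type when its posterior mean
#' expression exceeds \code{detectionFloor}. If any required subunit of an
#' assembly is not expressed the assembly is \code{absent}; otherwise the
#' fold ratio is max/min posterior mean over the distinct required subunits
#' (stoichiometry multiplicities do not weight it) and the class is
#' \code{within10} (ratio <= 10), \code{within100} (<= 100),
#' \code{within1000} (<= 1000), else \code{absent}.
#'
#' @param posterior an [ExpressionPosterior-class], or a named numeric
#'   vector of posterior mean expression per gene, or a genes x cell-types
#'   matrix of posterior means (then one call per column).
#' @param catalog a [PentamerCatalog-class]. Catalog genes missing from the
#'   posterior table are treated as not expressed.
#' @param thresholds increasing fold-range bounds, default c(10, 100, 1000).
#' @param detectionFloor posterior-mean expression below which a subunit
#'   counts as not expressed (default 0.1).
#' @return data.frame with columns \code{cellType}, \code{assembly},
#'   \code{class}, \code{minExpression}, \code{maxExpression}, \code{ratio}.
#' @examples
#' cat5 <- PentamerCatalog(list(a9a10 = c(chrna9 = 2, chrna10 = 3)))
#' repertoireClassify(c(chrna9 = 5, chrna10 = 3), cat5)
#' @export
repertoireClassify <- function(posterior, catalog,
                               thresholds = c(10, 100, 1000),
                               detectionFloor = 0.1) {
  stopifnot(is(catalog, "PentamerCatalog"))
  if (length(assemblies(catalog)) == 0) stop("empty catalog")
  if (any(diff(thresholds) <= 0)) stop("thresholds must be increasing")

  if (is(posterior, "ExpressionPosterior")) {
    means <- matrix(posteriorMean(posterior), ncol = 1,
                    dimnames = list(names(posteriorMean(posterior)),
                                    posterior@cellType))
  } else if (is.matrix(posterior)) {
    means <- posterior
  } else {
    means <- matrix(posterior, ncol = 1,
                    dimnames = list(names(posterior), "cellType1"))
  }

  classNames <- c(paste0("within", thresholds), "absent")
  out <- list()
  for (ct in colnames(means)) {
    mv <- means[, ct]
    for (asm in names(assemblies(catalog))) {
      genes <- names(assemblies(catalog)[[asm]])
      vals <- mv[genes]
      vals[is.na(vals)] <- 0                        # missing = not expressed
      if (any(vals <= detectionFloor)) {
        cls <- "absent"; ratio <- NA_real_
      } else {
        ratio <- max(vals) / min(vals)
        bin <- which(ratio <= thresholds)[1]
        cls <- if (is.na(bin)) "absent" else classNames[bin]
      }
      out[[length(out) + 1L]] <- data.frame(
        cellType = ct, assembly = asm, class = cls,
        minExpression = min(vals), maxExpression = max(vals), ratio = ratio)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Load the packaged pentamer assembly catalog
#'
#' A curated subset of literature-validated nAChR pentamers (homomeric
#' alpha7 and alpha9, the hair-cell (alpha9)2(alpha10)3 receptor, both
#' alpha4beta2 stoichiometries, alpha3beta4, alpha6beta2beta3, and the
#' muscle receptor). See the file header for provenance notes.
#'
#' @return a [PentamerCatalog-class].
#' @export
examplePentamerCatalog <- function() {
  PentamerCatalog(system.file("extdata", "pentamer_catalog.tsv",
                              package = "nachrevo", mustWork = TRUE))
}
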