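#' Assemble the receptor x property biophysical profile matrix
#'
#' Builds the ordered receptors x 5-properties matrix of mean values from a
#' long-format property table (columns \code{receptor}, \code{species},
#' \code{property}, \code{mean}). Rows are canonically ordered by receptor
#' subtype then species, so shuffled input yields an identical matrix. For
#' alpha4beta2, which has two dose-response components, the high-sensitivity
#' (smaller) EC50 enters the ACh-sensitivity column by default.
#'
#' @param table long-format data.frame, or a TSV path; defaults to the
#'   packaged biophysical property table.
#' @param ec50Component \code{"high"} (default) or \code{"low"}: which
#'   alpha4beta2 dose-response component fills the EC50 column.
#' @return numeric matrix, receptors (species_receptor rows) x properties
#'   \code{EC50}, \code{desensitization}, \code{ca_modulation},
#'   \code{ca_permeability}, \code{rectification}. Errors if any cell is
#'   missing.
#' @examples
#' m <- buildProfileTable()
#' m["frog_a9a10", "EC50"]       # 110.89
#' m["rat_a9a10", "rectification"]  # 1.21
#' @export
buildProfileTable <- function(table = NULL,
                              ec50Component = c("high", "low")) {
  ec50Component <- match.arg(ec50Component)
  if (is.null(table))
    table <- system.file("extdata", "biophysical_properties.tsv",
                         package = "nachrevo", mustWork = TRUE)
  if (is.character(table))
    table <- utils::read.delim(table, comment.char = "#",
                               stringsAsFactors = FALSE)
  need <- c("receptor", "species", "property", "mean")
  if (!all(need %in% colnames(table)))
    stop("property table needs columns: ", paste(need, collapse = ", "))

  # collapse the two-component EC50 to the requested component
  pick <- paste0("EC50_", ec50Component)
  table$property[table$property == pick] <- "EC50"
  table <- table[!(table$property %in% c("EC50_high", "EC50_low")), ]

  props <- c("EC50", "desensitization", "ca_modulation",
             "ca_permeability", "rectification")
  # canonical (sorted) row order so shuffled input yields the same matrix
  rows <- sort(unique(paste(table$species, table$receptor, sep = "_")))

  m <- matrix(NA_real_, length(rows), length(props),
              dimnames = list(rows, props))
  for (i in seq_len(nrow(table))) {
    rn <- paste(table$species[i], table$receptor[i], sep = "_")
    pn <- table$property[i]
    if (pn %in% props) m[rn, pn] <- table$mean[i]
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing property value(s): ",
         paste(rownames(m)[bad[, 1]], colnames(m)[bad[, 2]],
               sep = "/", collapse = ", "))
  }
  m
}

#' PCA of max-normalized functional profiles
#'
#' Each property column is divided by its maximum over receptors (equal
#' weighting), columns are centered, and the covariance (default) or
#' correlation eigendecomposition yields scores, loadings and explained
#' variance fractions.
#'
#' @param m receptors x properties numeric matrix (>= 2 rows and columns).
#' @param scale \code{"covariance"} (default) or \code{"correlation"}.
#' @return a [PCAModel-class].
#' @examples
#' fit <- pcaFit(buildProfileTable())
#' sum(varianceFractions(fit)[1:2])  # ~0.83
#' @export
pcaFit <- function(m, scale = c("covariance", "correlation")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(m), nrow(m) >= 2, ncol(m) >= 2)
  normConst <- apply(m, 2L, max)
  if (any(normConst == 0)) stop("zero-maximum property column: ",
                                paste(colnames(m)[normConst == 0], collapse = ", "))
  n <- sweep(m, 2L, normConst, `/`)
  centers <- colMeans(n)
  x <- sweep(n, 2L, centers, `-`)
  if (all(abs(x) < 1e-12)) stop("all-zero centered matrix: no variance to decompose")
  sdCols <- apply(x, 2L, stats::sd)
  if (any(sdCols == 0))
    stop("zero-variance property column after normalization: ",
         paste(colnames(m)[sdCols == 0], collapse = ", "))
  scaleSd <- if (scale == "correlation") sdCols else rep(1, ncol(m))
  names(scaleSd) <- colnames(m)
  x <- sweep(x, 2L, scaleSd, `/`)
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  v <- p$sdev^2
  new("PCAModel",
      normConstants = normConst,
      centers = centers,
      loadings = p$rotation,
      scores = p$x,
      varianceFractions = v / sum(v),
      scale = scale,
      scaleSd = scaleSd)
}

#' Project ancestral (or any supplementary) profiles into the extant PCA
#'
#' Applies the extant normalization constants and column centers to the
#' supplementary profiles and multiplies by the PC loadings; the extant
#' receptors' own profiles project onto exactly their scores, and the
#' extant column-mean profile projects to the origin.
#'
#' @param model a [PCAModel-class] fitted on the extant receptors.
#' @param profiles matrix (rows = supplementary receptors) or vector of
#'   property values on the original measurement scale, with columns
#'   matching the model's properties.
#' @param pcs which PCs to return coordinates for (default 1:2).
#' @return matrix of PC coordinates. A warning is issued when a profile
#'   lies outside 3 times the extant range of a property (extrapolation).
#' @export
projectAncestral <- function(model, profiles, pcs = 1:2) {
  stopifnot(is(model, "PCAModel"))
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, nrow = 1,
                       dimnames = list("anc", names(profiles)))
  props <- names(model@normConstants)
  if (!is.null(colnames(profiles))) {
    if (!all(props %in% colnames(profiles)))
      stop("profiles must provide all properties: ",
           paste(props, collapse = ", "))
    profiles <- profiles[, props, drop = FALSE]
  } else if (ncol(profiles) != length(props)) {
    stop("profiles must have ", length(props), " columns")
  }
  if (anyNA(profiles)) stop("ancestral profiles must be complete")

  # extant profiles on the original scale, for the extrapolation check
  extant <- model@scores %*% t(model@loadings)
  extant <- sweep(extant, 2L, model@scaleSd, `*`)
  extant <- sweep(sweep(extant, 2L, model@centers, `+`), 2L,
                  model@normConstants, `*`)
  rng <- apply(extant, 2L, range)
  span <- rng[2, ] - rng[1, ]
  lo <- rng[1, ] - 1.5 * span   # 3x the extant range, centered
  hi <- rng[2, ] + 1.5 * span
  outside <- sweep(profiles, 2L, lo, `<`) | sweep(profiles, 2L, hi, `>`)
  if (any(outside))
    warning("profile value(s) far outside the extant range (extrapolation): ",
            paste(unique(colnames(profiles)[which(outside, arr.ind = TRUE)[, 2]]),
                  collapse = ", "))

  x <- sweep(sweep(profiles, 2L, model@normConstants, `/`), 2L,
             model@centers, `-`)
  x <- sweep(x, 2L, model@scaleSd, `/`)
  x %*% model@loadings[, pcs, drop = FALSE]
}
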