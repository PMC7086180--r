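#' Fit the Hill dose-response equation
#'
#' Fits I/Imax = A^nH / (A^nH + EC50^nH) to normalized currents by nonlinear
#' least squares. With \code{components = 2}, the sum of two Hill terms with
#' a mixing fraction is fitted (the two-component dose-response typical of
#' receptors expressed at two stoichiometries).
#'
#' @param concentrations agonist concentrations (uM), >= 4 points spanning
#'   the EC50.
#' @param responses normalized currents in [0, 1.2].
#' @param components 1 (default) or 2.
#' @param imaxFree fit an Imax scale (default FALSE: responses are assumed
#'   normalized so the plateau is 1).
#' @return list with class \code{"hillFit"}: \code{ec50} (one or two values,
#'   ascending), \code{nH}, \code{fraction} (high-sensitivity component
#'   weight, 2-component fits), \code{imax}, per-parameter \code{se},
#'   \code{fitted}, \code{residuals}.
#' @examples
#' a <- 10^seq(-1, 3, length.out = 9)
#' y <- a / (a + 10)
#' hillFit(a, y)$ec50  # 10
#' @export
hillFit <- function(concentrations, responses, components = 1,
                    imaxFree = FALSE) {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 4)
    stop("need at least 4 concentration points")
  if (any(responses < -0.05) || any(responses > 1.2))
    stop("responses must be normalized currents in [0, 1.2]")
  if (any(concentrations <= 0)) stop("concentrations must be positive")

  df <- data.frame(a = concentrations, y = responses)
  ec0 <- stats::approx(responses, concentrations, xout = 0.5 * max(responses),
                       ties = mean)$y
  if (!is.finite(ec0)) ec0 <- stats::median(concentrations)

  if (components == 1) {
    fml <- if (imaxFree) y ~ imax * a^n / (a^n + e^n) else
      y ~ a^n / (a^n + e^n)
    start <- list(e = ec0, n = 1)
    if (imaxFree) start$imax <- max(responses)
    fit <- minpack.lm::nlsLM(fml, data = df, start = start,
                             lower = if (imaxFree) c(1e-9, 0.1, 0.1) else c(1e-9, 0.1),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, length(cf)))
    out <- list(ec50 = unname(cf["e"]), nH = unname(cf["n"]),
                fraction = 1,
                imax = if (imaxFree) unname(cf["imax"]) else 1,
                se = se, fitted = stats::fitted(fit),
                residuals = stats::residuals(fit))
  } else if (components == 2) {
    fml <- y ~ f * a^n1 / (a^n1 + e1^n1) + (1 - f) * a^n2 / (a^n2 + e2^n2)
    rng <- range(concentrations)
    start <- list(f = 0.5, e1 = max(ec0 / 10, rng[1]), n1 = 1,
                  e2 = min(ec0 * 10, rng[2]), n2 = 1)
    fit <- minpack.lm::nlsLM(fml, data = df, start = start,
                             lower = c(0, 1e-9, 0.1, 1e-9, 0.1),
                             upper = c(1, Inf, 10, Inf, 10),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, length(cf)))
    ec <- c(cf["e1"], cf["e2"]); nh <- c(cf["n1"], cf["n2"])
    fr <- unname(cf["f"])
    if (ec[1] > ec[2]) { ec <- rev(ec); nh <- rev(nh); fr <- 1 - fr }
    out <- list(ec50 = unname(ec), nH = unname(nh), fraction = fr,
                imax = 1, se = se, fitted = stats::fitted(fit),
                residuals = stats::residuals(fit))
  } else stop("components must be 1 or 2")

  conv <- fit$convInfo
  if (!is.null(conv) && !conv$isConv)
    stop("Hill fit did not converge; residual summary: ",
         paste(signif(summary(out$residuals), 3), collapse = " "))
  class(out) <- "hillFit"
  out
}

#' @export
print.hillFit <- function(x, ...) {
  cat("Hill fit:", length(x$ec50), "component(s)\n")
  for (i in seq_along(x$ec50))
    cat(sprintf("  EC50 = %.4g uM, nH = %.3g%s\n", x$ec50[i], x$nH[i],
                if (length(x$ec50) == 2)
                  sprintf(" (fraction %.2f)",
                          if (i == 1) x$fraction else 1 - x$fraction) else ""))
  invisible(x)
}
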