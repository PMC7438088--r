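#' Hertz force for spherical indentation
#'
#' Force of a rigid sphere of radius R indenting an elastic half-space by
#' depth delta: F = (4/3) (E / (1 - nu^2)) sqrt(R) delta^(3/2). The cell
#' is treated as incompressible by default (nu = 0.5).
#'
#' @param E Elastic modulus, Pa.
#' @param delta Indentation depth, m (vectorized, must be >= 0).
#' @param R Tip radius, m (assay default 3 um).
#' @param nu Poisson ratio.
#' @return Force, N.
#' @examples
#' hertzForce(1860, 0.5e-6)  # ~2.03 nN at 0.5 um indentation
#' @export
hertzForce <- function(E, delta, R = 3e-6, nu = 0.5) {
  if (any(delta < 0)) stop("indentation depth must be non-negative")
  if (E <= 0 || R <= 0) stop("E and R must be positive")
  if (nu < 0 || nu >= 1) stop("nu must lie in [0, 1)")
  4 / 3 * E / (1 - nu^2) * sqrt(R) * delta^1.5
}

#' Fit the Hertz model to a force-indentation curve
#'
#' Estimates the elastic modulus, contact point and force baseline from a
#' single approach curve. For a candidate contact point z0 the model
#' F = b + k (z - z0)^(3/2) for z > z0 (and F = b before contact) is
#' linear in (k, b), so the contact point is found by a grid search over
#' candidate offsets minimizing the residual sum of squares, then refined
#' jointly with (k, b) by nonlinear least squares. The fitted region is
#' restricted to indentations up to \code{fitFraction} of the maximum
#' indentation beyond contact. Curves with no detectable contact (best
#' slope k <= 0, or no meaningful improvement over a flat baseline) return
#' a non-converged fit.
#'
#' @param curve A \code{\link{forceCurve}}.
#' @param nu Poisson ratio used to convert the Hertz prefactor to E.
#' @param fitFraction Fraction of the post-contact indentation range used
#'   for fitting, in (0, 1].
#' @param nGrid Number of contact-point candidates in the grid search.
#' @return A \code{\link{HertzFit-class}} object.
#' @examples
#' cv <- makeForceCurves(1860)[[1]]
#' fitHertz(cv)
#' @export
fitHertz <- function(curve, nu = 0.5, fitFraction = 1, nGrid = 201) {
  stopifnot(is(curve, "ForceCurve"))
  validObject(curve)
  if (fitFraction <= 0 || fitFraction > 1)
    stop("fitFraction must lie in (0, 1]")
  z <- curve@z; F <- curve@force
  ord <- order(z); z <- z[ord]; F <- F[ord]
  n <- length(z)
  bad <- new("HertzFit", modulus = NA_real_, poisson = nu,
             contact = NA_real_, baseline = NA_real_, rss = NA_real_,
             converged = FALSE)
  if (n < 8) return(bad)

  # grid search: linear LS in (k, b) at each candidate contact point
  cand <- seq(z[1], z[n - 4], length.out = nGrid)
  best <- NULL
  for (z0 in cand) {
    delta <- pmax(0, z - z0)
    keep <- delta <= max(delta) * fitFraction
    X <- cbind(delta[keep]^1.5, 1)
    fitlm <- stats::lm.fit(X, F[keep])
    rss <- sum(fitlm$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(z0 = z0, k = unname(fitlm$coefficients[1]),
                   b = unname(fitlm$coefficients[2]), rss = rss)
  }
  # no-contact detection: Hertz fit must beat a flat baseline decisively
  rssFlat <- sum((F - mean(F)) ^ 2)
  if (!is.finite(best$k) || best$k <= 0 || best$rss > 0.9 * rssFlat)
    return(bad)

  refine <- tryCatch(minpack.lm::nls.lm(
    par = c(z0 = best$z0, k = best$k, b = best$b),
    fn = function(p) {
      delta <- pmax(0, z - p[1])
      keep <- delta <= max(delta) * fitFraction
      (p[3] + p[2] * delta^1.5 - F)[keep]
    },
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(refine) && refine$info %in% 1:4 && refine$par[["k"]] > 0) {
    pars <- refine$par; rss <- sum(refine$fvec^2)
  } else {
    pars <- c(z0 = best$z0, k = best$k, b = best$b); rss <- best$rss
  }
  E <- pars[["k"]] * 3 * (1 - nu^2) / (4 * sqrt(curve@tipRadius))
  new("HertzFit", modulus = E, poisson = nu, contact = pars[["z0"]],
      baseline = pars[["b"]], rss = rss, converged = TRUE)
}

#' Tabulate Hertz fits
#'
#' @param fits A list of \code{HertzFit}.
#' @param cellIds Optional identifiers (defaults to list names or index).
#' @return A data.frame with columns cell_id, E_Pa, nu, contact_m,
#'   baseline_N, rss, converged.
#' @export
hertzFitTable <- function(fits, cellIds = NULL) {
  if (is.null(cellIds))
    cellIds <- if (!is.null(names(fits))) names(fits) else
      as.character(seq_along(fits))
  do.call(rbind, Map(function(f, id)
    data.frame(cell_id = id, E_Pa = f@modulus, nu = f@poisson,
               contact_m = f@contact, baseline_N = f@baseline,
               rss = f@rss, converged = f@converged), fits, cellIds))
}

#' Read / write force curves as CSV
#'
#' One CSV per dataset with columns \code{cell_id}, \code{z_m},
#' \code{force_N} and a \code{tip_radius_m} column carrying the tip
#' radius.
#'
#' @param path CSV file path.
#' @return \code{readForceCurves}: a named list of \code{ForceCurve}.
#' @export
readForceCurves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$cell_id), function(d)
    forceCurve(d$z_m, d$force_N, tipRadius = d$tip_radius_m[1]))
  out[order(names(out))]
}

#' @rdname readForceCurves
#' @param curves A named list of \code{ForceCurve}.
#' @export
writeForceCurves <- function(curves, path) {
  ids <- if (!is.null(names(curves))) names(curves) else
    as.character(seq_along(curves))
  df <- do.call(rbind, Map(function(cv, id)
    data.frame(cell_id = id, z_m = cv@z, force_N = cv@force,
               tip_radius_m = cv@tipRadius), curves, ids))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
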