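#' Treatment-group presets
#'
#' Published group-level means and SDs used as generating truths by the
#' synthetic-data module: hyper- and hypo-osmotic hydraulic permeability
#' (m^3/(N s)), isotonic cell radius (um), AFM elastic modulus (kPa), and
#' the control-normalized circularity and pMLC intensity. Only values
#' printed in the source study's results text are hard-coded; quantities
#' reported only graphically (e.g. the ML7 circularity, the per-group
#' active water fractions) are NA and must be supplied by the user.
#' The reference active water fraction truth defaults to 0.6 for every
#' group (per-group values are not printed numerically).
#'
#' @return A data.frame with one row per treatment group.
#' @examples
#' groupPresets()
#' @export
groupPresets <- function() {
  data.frame(
    group = c("untreated", "TNFa", "blebbistatin", "Y27632", "ML7",
              "CN03+TNFa"),
    lp_hyper_mean = c(7.2, 10.5, 10.0, 8.3, 7.7, 4.4) * 1e-14,
    lp_hyper_sd   = c(1.4, 1.3, 2.1, 2.7, 2.9, 2.0) * 1e-14,
    lp_hypo_mean  = c(8.8, 10.4, NA, NA, NA, 5.9) * 1e-14,
    lp_hypo_sd    = c(1.4, 1.3, NA, NA, NA, 2.9) * 1e-14,
    radius_mean_um = c(9.1, 9.9, 9.5, 9.5, 9.12, 9.5),
    radius_sd_um   = c(1.3, 1.5, 1.4, 1.3, 1.3, NA),
    modulus_mean_kpa = c(1.86, 1.04, 1.05, 1.09, 2.25, 1.65),
    modulus_sd_kpa   = c(0.91, 0.52, 0.51, 0.53, 1.72, 0.88),
    circularity_rel = c(1.0, 0.746, 0.839, 0.836, NA, 1.167),
    pmlc_rel        = c(1.0, 0.804, NA, NA, NA, 1.123),
    phir_default    = 0.6,
    stringsAsFactors = FALSE)
}

# Truncated-normal sampling by rejection; bounds are physical, not tuned.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)), mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Draw a synthetic cell population from a group preset
#'
#' Draws per-cell biophysical truths (hyper/hypo Lp, isotonic radius,
#' elastic modulus, active water fraction) from truncated-normal
#' distributions at the preset group mean and SD, truncated at physical
#' bounds (Lp > 0, radius > 0, E > 0, phir in [0, 1]). Deterministic
#' under a fixed seed.
#'
#' @param group Group name as in \code{\link{groupPresets}}, or a
#'   one-row data.frame with the same columns.
#' @param n Number of cells.
#' @param seed Integer seed.
#' @param phir Mean active water fraction truth (default the preset's
#'   0.6).
#' @param phirSD SD of the phir truth (default 0: identical phir).
#' @return A data.frame with one row per cell: cell_id, group, lp_hyper,
#'   lp_hypo, radius_um, modulus_pa, phir.
#' @examples
#' samplePopulation("untreated", 5, seed = 1)
#' @export
samplePopulation <- function(group, n, seed = 1, phir = NULL,
                             phirSD = 0) {
  stopifnot(n >= 1)
  pre <- if (is.data.frame(group)) group else {
    gp <- groupPresets()
    row <- gp[gp$group == group, ]
    if (!nrow(row)) stop("unknown group '", group, "'")
    row
  }
  need <- c("lp_hyper_mean", "lp_hyper_sd", "radius_mean_um",
            "radius_sd_um", "modulus_mean_kpa", "modulus_sd_kpa")
  for (f in need)
    if (is.na(pre[[f]]))
      stop("preset field '", f, "' is NA for group '", pre$group,
           "' (value not printed in the source results); supply it ",
           "explicitly via a custom preset row")
  if (is.null(phir)) phir <- pre$phir_default
  set.seed(seed)
  lpHyper <- .rtruncnorm(n, pre$lp_hyper_mean, pre$lp_hyper_sd, lower = 0)
  lpHypo <- if (is.na(pre$lp_hypo_mean)) rep(NA_real_, n) else
    .rtruncnorm(n, pre$lp_hypo_mean, pre$lp_hypo_sd, lower = 0)
  radius <- .rtruncnorm(n, pre$radius_mean_um, pre$radius_sd_um,
                        lower = 0)
  modulus <- .rtruncnorm(n, pre$modulus_mean_kpa * 1e3,
                         pre$modulus_sd_kpa * 1e3, lower = 0)
  phirDraw <- .rtruncnorm(n, phir, phirSD, lower = 0, upper = 1)
  data.frame(cell_id = sprintf("%s_%03d", pre$group, seq_len(n)),
             group = pre$group, lp_hyper = lpHyper, lp_hypo = lpHypo,
             radius_um = radius, modulus_pa = modulus, phir = phirDraw,
             stringsAsFactors = FALSE)
}
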