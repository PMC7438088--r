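#' Volume-dependent surface area of a spherical cell
#'
#' The model treats the cell as a sphere, so the surface area follows from
#' the volume as A = 3 V / a with a = (3V / 4 pi)^(1/3), identical to
#' 4 pi a^2.
#'
#' @param V Cell volume, m^3 (vectorized).
#' @return Surface area, m^2.
#' @examples
#' surfaceArea(4 / 3 * pi * (1e-6)^3)  # sphere of radius 1 um -> 4pi um^2
#' @export
surfaceArea <- function(V) {
  if (any(!is.finite(V)) || any(V <= 0))
    stop("volume must be positive and finite")
  a <- (3 * V / (4 * pi))^(1 / 3)
  3 * V / a
}

#' Intracellular osmolarity from the mixture model
#'
#' Conservation of intracellular solute (the solute is nonpermeating, so
#' its molar amount ni is constant) together with the osmotically active
#' water fraction phi_i = 1 - (1 - phir) Vr / V gives the intracellular
#' osmolarity c_i = ni / (phi_i V). At the reference volume this reduces
#' to the reference osmolarity c_ir = ni / (phir Vr).
#'
#' @param V Current cell volume, m^3.
#' @param ni Moles of intracellular solute, mol (with osmolarities in
#'   mOsm/liter = mol/m^3, ni = c_ir * phir * Vr).
#' @param phir Reference active water fraction.
#' @param Vr Reference volume, m^3.
#' @return Intracellular osmolarity, mOsm/liter.
#' @examples
#' Vr <- 4 / 3 * pi * (9.1e-6)^3
#' ni <- 333 * 0.6 * Vr
#' intracellularOsmolarity(Vr, ni, 0.6, Vr)  # = 333
#' @export
intracellularOsmolarity <- function(V, ni, phir, Vr) {
  if (any(V <= 0) || ni <= 0 || Vr <= 0)
    stop("V, ni and Vr must be positive")
  if (phir < 0 || phir > 1) stop("phir must lie in [0, 1]")
  phii <- 1 - (1 - phir) * Vr / V
  if (any(phii <= 0))
    stop("degenerate state: cell volume at or below its solid fraction")
  ni / (phii * V)
}

#' Equilibrium volume ratio after an osmotic step
#'
#' In the limit dV/dt -> 0 the transport equation gives the closed-form
#' equilibrium ratio V_inf / Vr = 1 - phir + phir * c_er / c_e, where c_er
#' is the bath osmolarity the cell was equilibrated to before the step and
#' c_e the bath osmolarity during the step.
#'
#' @param phir Reference active water fraction, in [0, 1].
#' @param cer Reference (pre-step) bath osmolarity, mOsm/liter.
#' @param ce Step bath osmolarity, mOsm/liter.
#' @return The dimensionless ratio V_inf / Vr.
#' @examples
#' equilibriumVolumeRatio(1, 333, 466)    # 333/466
#' equilibriumVolumeRatio(0.5, 466, 333)  # swelling step
#' @export
equilibriumVolumeRatio <- function(phir, cer, ce) {
  if (any(phir < 0) || any(phir > 1)) stop("phir must lie in [0, 1]")
  if (any(cer <= 0) || any(ce <= 0)) stop("osmolarities must be positive")
  1 - phir + phir * cer / ce
}

#' Simulate the cell volume response to an osmotic protocol
#'
#' Numerically integrates the mixture-theory transport model
#' dV/dt = A(V) Lp R theta (c_i - c_e) through every step of the protocol.
#' The cell starts equilibrated with the equilibration bath (c_i = c_er at
#' V = Vr), the amount of intracellular solute is constant throughout (the
#' solute does not permeate), and the osmotically inactive volume
#' (1 - phir) Vr is fixed. \code{Lp} in \code{params} may give one value
#' per step. Integration uses an adaptive stiff-capable solver (lsoda)
#' with relative tolerance 1e-8.
#'
#' @param params A \code{\link{cellParams}} object.
#' @param protocol An \code{\link{OsmoticProtocol}}.
#' @param constants A \code{\link{modelConstants}} object.
#' @param samplingInterval Sampling interval of the output trace, s
#'   (default 2 s = 0.5 Hz).
#' @param cellId Identifier for the output trace.
#' @return A \code{\link{cellVolumeTrace}}. The first sample of each step
#'   is the step's reference state (for the first step, t = 0 at V = Vr).
#' @examples
#' tr <- simulateVolumeResponse(
#'   cellParams(Lp = 7.2e-14, phir = 0.6, refRadius = 9.1e-6),
#'   defaultProtocol(), modelConstants())
#' @export
simulateVolumeResponse <- function(params, protocol,
                                   constants = modelConstants(),
                                   samplingInterval = 2,
                                   cellId = "cell") {
  stopifnot(is(params, "CellParams"), is(protocol, "OsmoticProtocol"),
            is(constants, "ModelConstants"))
  validObject(params); validObject(protocol); validObject(constants)
  if (samplingInterval <= 0) stop("samplingInterval must be positive")

  nstep <- length(protocol@osmolarity)
  Lp <- rep_len(params@Lp, nstep)
  Vr <- 4 / 3 * pi * params@refRadius^3
  cer0 <- if (is.na(params@refOsmolarity)) protocol@equilibration else
    params@refOsmolarity
  ni <- cer0 * constants@osmScale * params@phir * Vr
  Vsolid <- (1 - params@phir) * Vr
  RT <- constants@gasConstant * constants@temperature

  labels <- stepLabels(protocol)
  time <- 0; volume <- Vr; lab <- labels[1]
  V0 <- Vr; tOffset <- 0
  for (s in seq_len(nstep)) {
    ce <- protocol@osmolarity[s] * constants@osmScale
    tloc <- seq(0, protocol@duration[s], by = samplingInterval)
    if (tloc[length(tloc)] < protocol@duration[s])
      tloc <- c(tloc, protocol@duration[s])
    V <- .integrateStep(V0, Lp[s], ni, Vsolid, ce, RT, tloc)
    # first local sample repeats the reference already emitted; the final
    # sample doubles as the next step's reference, so it carries the next
    # step's label
    nl <- length(tloc) - 1
    stepLab <- rep(labels[s], nl)
    if (s < nstep) stepLab[nl] <- labels[s + 1]
    time <- c(time, tOffset + tloc[-1])
    volume <- c(volume, V[-1])
    lab <- c(lab, stepLab)
    V0 <- V[length(V)]
    tOffset <- tOffset + protocol@duration[s]
  }
  cellVolumeTrace(cellId, time, volume, lab)
}

# Integrate one constant-bath step of the transport ODE. The active water
# volume V - Vsolid is kept away from zero so trial steps of the adaptive
# integrator cannot cross the singular state; a cell with no active water
# (ni = 0, phir = 0) cannot change volume at all.
.integrateStep <- function(V0, Lp, ni, Vsolid, ce, RT, times) {
  if (ni <= 0) return(rep(V0, length(times)))
  floorW <- 1e-6 * V0
  rhs <- function(t, y, p) {
    V <- y[1]
    a <- (3 * V / (4 * pi))^(1 / 3)
    phiiV <- max(V - Vsolid, floorW)
    ci <- ni / phiiV
    list((3 * V / a) * Lp * RT * (ci - ce))
  }
  out <- try(suppressWarnings(
    deSolve::ode(c(V = V0), times, rhs, NULL, method = "lsoda",
                 rtol = 1e-8, atol = V0 * 1e-12)), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times) ||
      any(!is.finite(out[, "V"])))
    stop("ODE integration failed; last valid state V = ",
         if (inherits(out, "try-error")) V0 else out[nrow(out), "V"])
  as.numeric(out[, "V"])
}

# Extract the samples of one labeled step from a trace.
.stepSlice <- function(trace, stepLabel) {
  idx <- which(trace@stepLabel == stepLabel)
  if (!length(idx))
    stop("protocol mismatch: step '", stepLabel, "' not present in trace ",
         "of cell '", trace@cellId, "'")
  list(time = trace@time[idx] - trace@time[idx[1]],
       volume = trace@volume[idx])
}

#' Estimate the active water fraction from the equilibrium plateau
#'
#' Inverts the closed-form equilibrium relation: with the plateau ratio
#' V_inf / Vr measured from the trace,
#' phir = (V_inf / Vr - 1) / (c_er / c_e - 1). V_inf is the mean volume
#' over the final \code{plateauWindow} seconds of the step; the step must
#' actually plateau (volume change below \code{plateauTol} over that
#' window), otherwise a QC error is raised. Estimates outside [0, 1] are
#' clamped and flagged.
#'
#' @param trace A \code{\link{cellVolumeTrace}}.
#' @param stepLabel Which step of the trace to use.
#' @param cer Pre-step (reference) bath osmolarity, mOsm/liter.
#' @param ce Step bath osmolarity, mOsm/liter.
#' @param plateauWindow Length of the terminal window, s.
#' @param plateauTol Maximum relative volume change over the window.
#' @return A list with \code{phir}, \code{ratio} (V_inf / Vr) and
#'   \code{clamped}.
#' @export
estimatePhirFromEquilibrium <- function(trace, stepLabel, cer, ce,
                                        plateauWindow = 30,
                                        plateauTol = 0.05) {
  if (cer == ce)
    stop("unidentifiable: reference and step osmolarity are equal")
  sl <- .stepSlice(trace, stepLabel)
  tail_idx <- sl$time >= max(sl$time) - plateauWindow
  Vtail <- sl$volume[tail_idx]
  if (length(Vtail) >= 2 &&
      abs(max(Vtail) - min(Vtail)) / Vtail[length(Vtail)] > plateauTol)
    stop("no plateau reached in step '", stepLabel,
         "': volume still changing over the final window")
  ratio <- mean(Vtail) / sl$volume[1]
  phir <- (ratio - 1) / (cer / ce - 1)
  clamped <- phir < 0 || phir > 1
  list(phir = min(1, max(0, phir)), ratio = ratio, clamped = clamped)
}

#' Fit the mixture-theory volume model to one osmotic step
#'
#' Jointly estimates (Lp, phir) by nonlinear least squares of the measured
#' normalized volume V(t)/V(0) against the integrated transport model. The
#' cell is assumed osmotically equilibrated with the pre-step bath at the
#' start of the step, so c_ir = c_er. The reference volume Vr is treated
#' as a nuisance scale parameter initialized at the first sample of the
#' step and refined jointly: anchoring it to the single (noisy) first
#' measurement would propagate that sample's error into every residual
#' and alias into Lp and phir. phir is initialized from the equilibrium
#' plateau when one exists, Lp from a coarse profile scan; box bounds are
#' Lp in [1e-16, 1e-11] (fitted on log10 scale), phir in [0, 1], and the
#' reference scale within 20% of the first sample.
#'
#' @param trace A \code{\link{cellVolumeTrace}}.
#' @param stepLabel Which labeled step to fit.
#' @param cer Pre-step (reference) bath osmolarity, mOsm/liter.
#' @param ce Step bath osmolarity, mOsm/liter.
#' @param constants A \code{\link{modelConstants}}.
#' @param init Optional named list \code{list(Lp=, phir=)} of starting
#'   values.
#' @param bounds Named list \code{list(Lp = c(lo, hi), phir = c(lo, hi))}.
#' @param qcPlateauWindow,qcPlateauTol Plateau QC rule: flag the fit
#'   "no_plateau" when the volume changes by more than \code{qcPlateauTol}
#'   (relative) over the final \code{qcPlateauWindow} seconds; bursting
#'   cells fail this rule.
#' @param qcMinR2 Fits with R^2 below this are flagged "low_r2".
#' @return A \code{\link{MixtureFitResult-class}} object.
#' @examples
#' pr <- defaultProtocol()
#' tr <- simulateVolumeResponse(
#'   cellParams(Lp = 7.2e-14, phir = 0.6, refRadius = 9.1e-6), pr)
#' fitMixtureModel(tr, "hyper", cer = 333, ce = 466)
#' @export
fitMixtureModel <- function(trace, stepLabel, cer, ce,
                            constants = modelConstants(),
                            init = NULL,
                            bounds = list(Lp = c(1e-16, 1e-11),
                                          phir = c(0, 1)),
                            qcPlateauWindow = 30, qcPlateauTol = 0.05,
                            qcMinR2 = 0.8) {
  sl <- .stepSlice(trace, stepLabel)
  if (length(sl$time) < 10)
    stop("need at least 10 samples within the step to fit")
  flags <- character()
  empty <- function(flags) new("MixtureFitResult", cellId = trace@cellId,
    stepLabel = stepLabel, Lp = NA_real_, phir = NA_real_,
    rss = NA_real_, r2 = NA_real_, converged = FALSE, qcFlags = flags)

  if (cer == ce) return(empty(c(flags, "unidentifiable")))
  vobs <- sl$volume / sl$volume[1]
  if (max(abs(vobs - 1)) < 1e-6)
    return(empty(c(flags, "unidentifiable", "flat_trace")))

  Vr <- sl$volume[1]
  RT <- constants@gasConstant * constants@temperature
  ceSI <- ce * constants@osmScale
  cerSI <- cer * constants@osmScale

  phir0 <- tryCatch(
    estimatePhirFromEquilibrium(trace, stepLabel, cer, ce)$phir,
    error = function(e) 0.6)
  phir0 <- min(0.99, max(0.01, phir0))
  Lp0 <- 1e-13
  if (!is.null(init)) {
    if (!is.null(init$Lp)) Lp0 <- init$Lp
    if (!is.null(init$phir)) phir0 <- init$phir
  }

  # p = (log10 Lp, phir, s) with s the reference-volume scale: the model
  # trace is integrated from s * V(0) and compared with V(t) / V(0)
  model <- function(lLp, phir, s) {
    ni <- cerSI * phir * Vr
    Vsolid <- (1 - phir) * Vr
    s * .integrateStep(Vr, 10^lLp, ni, Vsolid, ceSI, RT, sl$time) / Vr
  }
  resid <- function(p) {
    vm <- tryCatch(model(p[1], p[2], p[3]), error = function(e) NULL)
    if (is.null(vm)) return(rep(1e3, length(vobs)))
    vm - vobs
  }
  # coarse profile over Lp at the plateau-based phir to land the local
  # optimizer in the right basin even for noisy traces
  if (is.null(init) || is.null(init$Lp)) {
    lgrid <- seq(-14.5, -12, by = 0.5)
    rssGrid <- vapply(lgrid, function(l) sum(resid(c(l, phir0, 1))^2),
                      numeric(1))
    Lp0 <- 10^lgrid[which.min(rssGrid)]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(lLp = log10(Lp0), phir = phir0, s = 1),
                       lower = c(log10(bounds$Lp[1]), bounds$phir[1], 0.8),
                       upper = c(log10(bounds$Lp[2]), bounds$phir[2], 1.2),
                       fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4)
    return(empty(c(flags, "nonconverged")))

  rss <- sum(fit$fvec^2)
  r2 <- 1 - rss / sum((vobs - mean(vobs))^2)
  # plateau / burst QC on the data
  tail_idx <- sl$time >= max(sl$time) - qcPlateauWindow
  Vtail <- sl$volume[tail_idx]
  if (length(Vtail) >= 2 &&
      abs(max(Vtail) - min(Vtail)) / Vtail[length(Vtail)] > qcPlateauTol)
    flags <- c(flags, "no_plateau")
  if (is.finite(r2) && r2 < qcMinR2) flags <- c(flags, "low_r2")
  phirHat <- fit$par[["phir"]]
  if (phirHat <= bounds$phir[1] + 1e-9 || phirHat >= bounds$phir[2] - 1e-9)
    flags <- c(flags, "phir_at_bound")
  LpHat <- 10^fit$par[["lLp"]]
  if (LpHat <= bounds$Lp[1] * 1.01 || LpHat >= bounds$Lp[2] * 0.99)
    flags <- c(flags, "lp_at_bound")

  new("MixtureFitResult", cellId = trace@cellId, stepLabel = stepLabel,
      Lp = 10^fit$par[["lLp"]], phir = phirHat, rss = rss, r2 = r2,
      converged = TRUE, qcFlags = flags)
}

#' Fit every step of a protocol, resetting the reference state per step
#'
#' Splits the trace by step label and fits each step independently with
#' \code{\link{fitMixtureModel}}. The reference state (Vr, c_ir) is reset
#' at the start of each step: the first sample of the step provides Vr and
#' the preceding bath provides c_er, mirroring the analysis done per
#' osmotic loading step.
#'
#' @param trace A \code{\link{cellVolumeTrace}}.
#' @param protocol The \code{\link{OsmoticProtocol}} used to acquire it.
#' @param constants A \code{\link{modelConstants}}.
#' @param ... Passed on to \code{\link{fitMixtureModel}}.
#' @return A named list of \code{MixtureFitResult}, one per step.
#' @export
fitTwoStepSequence <- function(trace, protocol,
                               constants = modelConstants(), ...) {
  labels <- stepLabels(protocol)
  prev <- c(protocol@equilibration,
            protocol@osmolarity[-length(protocol@osmolarity)])
  missing <- setdiff(labels, unique(trace@stepLabel))
  if (length(missing))
    stop("protocol mismatch: step(s) ", paste(missing, collapse = ", "),
         " not present in trace of cell '", trace@cellId, "'")
  res <- lapply(seq_along(labels), function(s)
    fitMixtureModel(trace, labels[s], cer = prev[s],
                    ce = protocol@osmolarity[s], constants = constants,
                    ...))
  names(res) <- labels
  res
}

#' Tabulate mixture-model fit results
#'
#' @param results A list of \code{MixtureFitResult} (possibly nested lists
#'   as returned by \code{\link{fitTwoStepSequence}} over many cells).
#' @return A data.frame with one row per cell per step: cell_id,
#'   step_label, Lp, phir, rss, r2, converged, qc_flags.
#' @export
mixtureFitTable <- function(results) {
  flat <- list()
  rec <- function(x) {
    if (is(x, "MixtureFitResult")) flat[[length(flat) + 1]] <<- x
    else if (is.list(x)) lapply(x, rec)
  }
  rec(results)
  do.call(rbind, lapply(flat, function(f)
    data.frame(cell_id = f@cellId, step_label = f@stepLabel, Lp = f@Lp,
               phir = f@phir, rss = f@rss, r2 = f@r2,
               converged = f@converged,
               qc_flags = paste(f@qcFlags, collapse = ";"))))
}

#' Read / write volume traces as CSV
#'
#' Traces are exchanged as tidy CSV with columns \code{cell_id},
#' \code{t_s}, \code{volume_m3} (or \code{radius_um}, converted via the
#' sphere relation), and \code{step_label}.
#'
#' @param path CSV file path.
#' @return \code{readVolumeTraces}: a named list of
#'   \code{CellVolumeTrace}; \code{writeVolumeTraces}: invisibly, the
#'   path.
#' @export
readVolumeTraces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"volume_m3" %in% names(df)) {
    if (!"radius_um" %in% names(df))
      stop("CSV must contain volume_m3 or radius_um")
    df$volume_m3 <- 4 / 3 * pi * (df$radius_um * 1e-6)^3
  }
  out <- lapply(split(df, df$cell_id), function(d)
    cellVolumeTrace(d$cell_id[1], d$t_s, d$volume_m3, d$step_label))
  out[order(names(out))]
}

#' @rdname readVolumeTraces
#' @param traces A list of \code{CellVolumeTrace}.
#' @export
writeVolumeTraces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr@cellId, t_s = tr@time, volume_m3 = tr@volume,
               step_label = tr@stepLabel)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
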