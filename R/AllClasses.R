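#' @import methods
NULL

#' Physical constants for the osmotic volume-response model
#'
#' Container for the universal gas constant, absolute temperature, and the
#' conversion between the reported osmolarity unit (mOsm/liter) and SI
#' (mol/m^3). With the convention that 1 mOsm/liter of osmotically active
#' solute equals 1 mol/m^3, the conversion factor is exactly 1, so
#' osmolarities can be carried in mOsm/liter throughout and the product
#' R * theta * c is a pressure in Pa.
#'
#' @slot gasConstant Universal gas constant R, J/(mol K).
#' @slot temperature Absolute temperature theta, K. Osmotic loading is done
#'   at room temperature, so the default is 295.15 K.
#' @slot osmScale Conversion factor from mOsm/liter to mol/m^3 (1.0).
#' @export
setClass("ModelConstants",
  representation(gasConstant = "numeric", temperature = "numeric",
                 osmScale = "numeric"),
  prototype(gasConstant = 8.314, temperature = 295.15, osmScale = 1.0))

setValidity("ModelConstants", function(object) {
  if (length(object@gasConstant) != 1 || object@gasConstant <= 0)
    return("gasConstant must be a single positive number")
  if (length(object@temperature) != 1 || object@temperature <= 0)
    return("temperature must be a single positive number (K)")
  if (length(object@osmScale) != 1 || object@osmScale <= 0)
    return("osmScale must be a single positive number")
  TRUE
})

#' @describeIn ModelConstants-class Constructor.
#' @param temperature Absolute temperature in K.
#' @param gasConstant Gas constant in J/(mol K).
#' @param osmScale mOsm/liter to mol/m^3 conversion.
#' @return A \code{ModelConstants} object.
#' @examples
#' modelConstants()
#' @export
modelConstants <- function(temperature = 295.15, gasConstant = 8.314,
                           osmScale = 1.0) {
  new("ModelConstants", gasConstant = gasConstant,
      temperature = temperature, osmScale = osmScale)
}

#' Osmotic loading protocol
#'
#' An ordered sequence of extracellular osmolarity steps with durations,
#' preceded by an equilibration bath. The default reproduces the standard
#' assay: equilibrate at 333 mOsm/liter, a hyperosmotic step to 466
#' mOsm/liter, then a hypo-osmotic step back to 333 mOsm/liter, 5 minutes
#' each.
#'
#' @slot osmolarity Extracellular osmolarity of each step, mOsm/liter.
#' @slot duration Duration of each step, s.
#' @slot equilibration Osmolarity of the equilibration bath preceding the
#'   first step, mOsm/liter.
#' @export
setClass("OsmoticProtocol",
  representation(osmolarity = "numeric", duration = "numeric",
                 equilibration = "numeric"))

setValidity("OsmoticProtocol", function(object) {
  if (length(object@osmolarity) < 1)
    return("protocol needs at least one step")
  if (length(object@osmolarity) != length(object@duration))
    return("osmolarity and duration must have the same length")
  if (any(object@osmolarity <= 0) || object@equilibration <= 0)
    return("all osmolarities must be positive")
  if (any(object@duration <= 0))
    return("all step durations must be positive")
  TRUE
})

#' @describeIn OsmoticProtocol-class Constructor.
#' @param osmolarity Numeric vector of step osmolarities, mOsm/liter.
#' @param duration Numeric vector of step durations, s.
#' @param equilibration Equilibration osmolarity, mOsm/liter.
#' @return An \code{OsmoticProtocol}.
#' @examples
#' defaultProtocol()
#' @export
OsmoticProtocol <- function(osmolarity, duration, equilibration = 333) {
  new("OsmoticProtocol", osmolarity = as.numeric(osmolarity),
      duration = as.numeric(duration),
      equilibration = as.numeric(equilibration))
}

#' @describeIn OsmoticProtocol-class The standard two-step protocol
#'   (333 -> 466 -> 333 mOsm/liter, 300 s per step).
#' @export
defaultProtocol <- function() {
  OsmoticProtocol(osmolarity = c(466, 333), duration = c(300, 300),
                  equilibration = 333)
}

#' Per-cell biophysical parameters of the volume-response model
#'
#' Hydraulic permeability Lp, reference osmotically active water fraction
#' phir, and the reference geometry. \code{Lp} may hold one value per
#' protocol step (e.g. different hyper- and hypo-osmotic permeabilities);
#' a single value is recycled. The reference volume is tied to the
#' reference radius by the sphere relation V = (4/3) pi a^3.
#'
#' @slot Lp Hydraulic permeability, m^3/(N s); one value or one per step.
#' @slot phir Reference osmotically active water fraction, in [0, 1].
#' @slot refRadius Reference cell radius, m.
#' @slot refOsmolarity Intracellular osmolarity in the reference state,
#'   mOsm/liter (NA to take it from the protocol's equilibration bath).
#' @export
setClass("CellParams",
  representation(Lp = "numeric", phir = "numeric", refRadius = "numeric",
                 refOsmolarity = "numeric"),
  prototype(refOsmolarity = NA_real_))

setValidity("CellParams", function(object) {
  if (any(object@Lp <= 0)) return("Lp must be positive")
  if (length(object@phir) != 1 || object@phir < 0 || object@phir > 1)
    return("phir must be a single value in [0, 1]")
  if (length(object@refRadius) != 1 || object@refRadius <= 0)
    return("refRadius must be a single positive length (m)")
  if (!is.na(object@refOsmolarity) && object@refOsmolarity <= 0)
    return("refOsmolarity must be positive when given")
  TRUE
})

#' @describeIn CellParams-class Constructor.
#' @param Lp Hydraulic permeability, m^3/(N s).
#' @param phir Reference active water fraction.
#' @param refRadius Reference radius, m.
#' @param refOsmolarity Reference intracellular osmolarity, mOsm/liter.
#' @return A \code{CellParams}.
#' @examples
#' cellParams(Lp = 7.2e-14, phir = 0.6, refRadius = 9.1e-6)
#' @export
cellParams <- function(Lp, phir, refRadius, refOsmolarity = NA_real_) {
  new("CellParams", Lp = Lp, phir = phir, refRadius = refRadius,
      refOsmolarity = refOsmolarity)
}

#' Single-cell volume trace under osmotic loading
#'
#' A per-cell time series of volume with its sampling metadata and a step
#' label per time point. Time is strictly increasing; the default assay
#' samples at 0.5 Hz (2 s interval).
#'
#' @slot cellId Character cell identifier.
#' @slot time Time points, s.
#' @slot volume Cell volume, m^3.
#' @slot stepLabel Character label per time point (e.g. "hyper", "hypo").
#' @export
setClass("CellVolumeTrace",
  representation(cellId = "character", time = "numeric",
                 volume = "numeric", stepLabel = "character"))

setValidity("CellVolumeTrace", function(object) {
  n <- length(object@time)
  if (length(object@volume) != n || length(object@stepLabel) != n)
    return("time, volume and stepLabel must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    return("time must be strictly increasing")
  if (any(object@volume <= 0))
    return("all volumes must be positive")
  TRUE
})

#' @describeIn CellVolumeTrace-class Constructor.
#' @param cellId Cell identifier.
#' @param time Time points, s.
#' @param volume Volumes, m^3.
#' @param stepLabel Step label per time point.
#' @return A \code{CellVolumeTrace}.
#' @export
cellVolumeTrace <- function(cellId, time, volume, stepLabel) {
  new("CellVolumeTrace", cellId = as.character(cellId),
      time = as.numeric(time), volume = as.numeric(volume),
      stepLabel = as.character(stepLabel))
}

#' Result of fitting the mixture-theory volume model to one osmotic step
#'
#' Per-step estimates of Lp and phir together with fit diagnostics and QC
#' flags. When the fit fails to converge or the step is unidentifiable the
#' estimates are NA and \code{converged} is FALSE.
#'
#' @slot cellId Cell identifier.
#' @slot stepLabel Which step was fitted.
#' @slot Lp Fitted hydraulic permeability, m^3/(N s).
#' @slot phir Fitted reference active water fraction.
#' @slot rss Residual sum of squares on normalized volume.
#' @slot r2 Coefficient of determination of the fit.
#' @slot converged Logical convergence flag.
#' @slot qcFlags Character vector of QC annotations ("no_plateau",
#'   "low_r2", "phir_clamped", "unidentifiable", ...); empty when clean.
#' @export
setClass("MixtureFitResult",
  representation(cellId = "character", stepLabel = "character",
                 Lp = "numeric", phir = "numeric", rss = "numeric",
                 r2 = "numeric", converged = "logical",
                 qcFlags = "character"))

setValidity("MixtureFitResult", function(object) {
  if (length(object@converged) != 1) return("converged must be scalar")
  if (!is.na(object@r2) && object@r2 > 1)
    return("r2 cannot exceed 1")
  TRUE
})

#' AFM force-indentation curve
#'
#' Samples of cantilever force against piezo displacement (or indentation)
#' acquired with a spherical tip. Displacement increases towards the
#' sample, with the contact point somewhere along the sweep.
#'
#' @slot z Piezo displacement samples, m.
#' @slot force Force samples, N.
#' @slot tipRadius Radius of the spherical tip, m (assay default 3 um).
#' @export
setClass("ForceCurve",
  representation(z = "numeric", force = "numeric", tipRadius = "numeric"))

setValidity("ForceCurve", function(object) {
  if (length(object@z) != length(object@force))
    return("z and force must have equal length")
  if (length(object@tipRadius) != 1 || object@tipRadius <= 0)
    return("tipRadius must be a single positive length (m)")
  TRUE
})

#' @describeIn ForceCurve-class Constructor.
#' @param z Displacement samples, m.
#' @param force Force samples, N.
#' @param tipRadius Tip radius, m.
#' @return A \code{ForceCurve}.
#' @export
forceCurve <- function(z, force, tipRadius = 3e-6) {
  new("ForceCurve", z = as.numeric(z), force = as.numeric(force),
      tipRadius = tipRadius)
}

#' Fitted Hertz spherical-indentation model
#'
#' @slot modulus Elastic modulus E, Pa.
#' @slot poisson Poisson ratio used in the fit.
#' @slot contact Contact-point offset along z, m.
#' @slot baseline Force baseline, N.
#' @slot rss Residual sum of squares, N^2.
#' @slot converged Logical convergence flag.
#' @export
setClass("HertzFit",
  representation(modulus = "numeric", poisson = "numeric",
                 contact = "numeric", baseline = "numeric",
                 rss = "numeric", converged = "logical"))

#' Labeled segmentation mask
#'
#' Integer label image from cell segmentation, with its physical pixel
#' size. Label 0 is background; labels >= 1 are cell objects.
#'
#' @slot labels Integer matrix of object labels.
#' @slot pixelSize Pixel size, um/pixel (assay default 0.2).
#' @slot frame Frame index within a sequence.
#' @export
setClass("LabeledMask",
  representation(labels = "matrix", pixelSize = "numeric",
                 frame = "integer"),
  prototype(pixelSize = 0.2, frame = 1L))

setValidity("LabeledMask", function(object) {
  if (any(object@labels < 0)) return("labels must be >= 0")
  if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/pixel)")
  TRUE
})

#' @describeIn LabeledMask-class Constructor.
#' @param labels Integer matrix of labels (0 = background).
#' @param pixelSize Pixel size, um/pixel.
#' @param frame Frame index.
#' @return A \code{LabeledMask}.
#' @export
labeledMask <- function(labels, pixelSize = 0.2, frame = 1L) {
  storage.mode(labels) <- "integer"
  new("LabeledMask", labels = labels, pixelSize = pixelSize,
      frame = as.integer(frame))
}

#' Single-cell gating configuration
#'
#' Thresholds used to keep single, in-focus, well-exposed cells and drop
#' fragments, debris and multicellular clusters, mirroring the gating done
#' on imaging flow cytometry feature tables.
#'
#' @slot minArea Minimum mask area, um^2 (drops fragments/debris).
#' @slot maxArea Maximum mask area, um^2 (drops large clusters).
#' @slot maxAspect Maximum ellipse aspect ratio (drops doublets).
#' @slot minFocus Minimum sharpness (variance-of-Laplacian style) score;
#'   NA disables the focus gate.
#' @slot intensityRange Two-element under/over-range bounds on total
#'   intensity; NA disables.
#' @export
setClass("GateConfig",
  representation(minArea = "numeric", maxArea = "numeric",
                 maxAspect = "numeric", minFocus = "numeric",
                 intensityRange = "numeric"),
  prototype(minArea = 80, maxArea = 1500, maxAspect = 1.4,
            minFocus = NA_real_, intensityRange = c(NA_real_, NA_real_)))

setValidity("GateConfig", function(object) {
  if (object@minArea >= object@maxArea)
    return("minArea must be smaller than maxArea")
  if (object@maxAspect < 1) return("maxAspect must be >= 1")
  TRUE
})

#' @describeIn GateConfig-class Constructor.
#' @param minArea,maxArea Area gates, um^2.
#' @param maxAspect Aspect-ratio gate.
#' @param minFocus Optional sharpness gate.
#' @param intensityRange Optional total-intensity bounds.
#' @return A \code{GateConfig}.
#' @export
gateConfig <- function(minArea = 80, maxArea = 1500, maxAspect = 1.4,
                       minFocus = NA_real_,
                       intensityRange = c(NA_real_, NA_real_)) {
  new("GateConfig", minArea = minArea, maxArea = maxArea,
      maxAspect = maxAspect, minFocus = minFocus,
      intensityRange = intensityRange)
}
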