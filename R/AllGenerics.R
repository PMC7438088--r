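#' Accessors and show methods
#'
#' Small accessor generics for the core S4 containers, so user code never
#' reaches into slots directly.
#'
#' @param object An object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("osmSteps", function(object) standardGeneric("osmSteps"))

#' @rdname accessors
#' @export
setMethod("osmSteps", "OsmoticProtocol", function(object) {
  data.frame(step = seq_along(object@osmolarity),
             label = stepLabels(object),
             osmolarity = object@osmolarity,
             duration = object@duration)
})

#' @rdname accessors
#' @export
setGeneric("equilibrationOsm",
           function(object) standardGeneric("equilibrationOsm"))

#' @rdname accessors
#' @export
setMethod("equilibrationOsm", "OsmoticProtocol",
          function(object) object@equilibration)

#' Step labels of a protocol
#'
#' Labels each step "hyper", "hypo" or "iso" by comparing its osmolarity
#' with the preceding bath (equilibration for the first step). Repeated
#' directions get a numeric suffix.
#'
#' @param protocol An \code{OsmoticProtocol}.
#' @return Character vector, one label per step.
#' @examples
#' stepLabels(defaultProtocol())
#' @export
stepLabels <- function(protocol) {
  prev <- c(protocol@equilibration,
            protocol@osmolarity[-length(protocol@osmolarity)])
  lab <- ifelse(protocol@osmolarity > prev, "hyper",
                ifelse(protocol@osmolarity < prev, "hypo", "iso"))
  dup <- stats::ave(seq_along(lab), lab, FUN = seq_along)
  ifelse(duplicated(lab) | duplicated(lab, fromLast = TRUE),
         paste0(lab, dup), lab)
}

#' @rdname accessors
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))

#' @rdname accessors
#' @export
setMethod("cellId", "CellVolumeTrace", function(object) object@cellId)

#' @rdname accessors
#' @export
setMethod("cellId", "MixtureFitResult", function(object) object@cellId)

#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))

#' @rdname accessors
#' @export
setMethod("traceTime", "CellVolumeTrace", function(object) object@time)

#' @rdname accessors
#' @export
setGeneric("traceVolume", function(object) standardGeneric("traceVolume"))

#' @rdname accessors
#' @export
setMethod("traceVolume", "CellVolumeTrace", function(object) object@volume)

#' @rdname accessors
#' @export
setGeneric("traceStepLabel",
           function(object) standardGeneric("traceStepLabel"))

#' @rdname accessors
#' @export
setMethod("traceStepLabel", "CellVolumeTrace",
          function(object) object@stepLabel)

#' @rdname accessors
#' @export
setGeneric("hydraulicPermeability",
           function(object) standardGeneric("hydraulicPermeability"))

#' @rdname accessors
#' @export
setMethod("hydraulicPermeability", "MixtureFitResult",
          function(object) object@Lp)

#' @rdname accessors
#' @export
setMethod("hydraulicPermeability", "CellParams", function(object) object@Lp)

#' @rdname accessors
#' @export
setGeneric("activeWaterFraction",
           function(object) standardGeneric("activeWaterFraction"))

#' @rdname accessors
#' @export
setMethod("activeWaterFraction", "MixtureFitResult",
          function(object) object@phir)

#' @rdname accessors
#' @export
setMethod("activeWaterFraction", "CellParams", function(object) object@phir)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setMethod("isConverged", "MixtureFitResult",
          function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("isConverged", "HertzFit", function(object) object@converged)

#' @rdname accessors
#' @export
setGeneric("qcFlags", function(object) standardGeneric("qcFlags"))

#' @rdname accessors
#' @export
setMethod("qcFlags", "MixtureFitResult", function(object) object@qcFlags)

#' @rdname accessors
#' @export
setGeneric("elasticModulus",
           function(object) standardGeneric("elasticModulus"))

#' @rdname accessors
#' @export
setMethod("elasticModulus", "HertzFit", function(object) object@modulus)

#' @rdname accessors
#' @export
setGeneric("contactPoint", function(object) standardGeneric("contactPoint"))

#' @rdname accessors
#' @export
setMethod("contactPoint", "HertzFit", function(object) object@contact)

#' @rdname accessors
#' @export
setGeneric("tipRadius", function(object) standardGeneric("tipRadius"))

#' @rdname accessors
#' @export
setMethod("tipRadius", "ForceCurve", function(object) object@tipRadius)

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))

#' @rdname accessors
#' @export
setMethod("maskLabels", "LabeledMask", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setMethod("pixelSize", "LabeledMask", function(object) object@pixelSize)

setMethod("show", "OsmoticProtocol", function(object) {
  cat("OsmoticProtocol: equilibrate at", object@equilibration,
      "mOsm/liter\n")
  st <- osmSteps(object)
  for (i in seq_len(nrow(st)))
    cat(sprintf("  step %d [%s]: %g mOsm/liter for %g s\n", st$step[i],
                st$label[i], st$osmolarity[i], st$duration[i]))
})

setMethod("show", "CellParams", function(object) {
  cat("CellParams:\n",
      sprintf("  Lp      = %s m^3/(N s)\n",
              paste(signif(object@Lp, 4), collapse = ", ")),
      sprintf("  phir    = %.3f\n", object@phir),
      sprintf("  radius  = %.2f um\n", object@refRadius * 1e6), sep = "")
})

setMethod("show", "CellVolumeTrace", function(object) {
  cat(sprintf("CellVolumeTrace '%s': %d samples, %.0f-%.0f s, steps: %s\n",
              object@cellId, length(object@time), min(object@time),
              max(object@time),
              paste(unique(object@stepLabel), collapse = ", ")))
})

setMethod("show", "MixtureFitResult", function(object) {
  cat(sprintf(
    "MixtureFitResult '%s' [%s]: Lp = %s m^3/(N s), phir = %.3f, R2 = %.4f%s\n",
    object@cellId, object@stepLabel, signif(object@Lp, 4), object@phir,
    object@r2,
    if (length(object@qcFlags)) paste0(" (",
      paste(object@qcFlags, collapse = ","), ")") else ""))
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve: %d samples, tip radius %.1f um, max force %.3g nN\n",
              length(object@z), object@tipRadius * 1e6,
              max(object@force) * 1e9))
})

setMethod("show", "HertzFit", function(object) {
  cat(sprintf(
    "HertzFit: E = %.3g kPa (nu = %.2f), contact = %.1f nm, converged = %s\n",
    object@modulus / 1e3, object@poisson, object@contact * 1e9,
    object@converged))
})

setMethod("show", "LabeledMask", function(object) {
  cat(sprintf("LabeledMask: %d x %d px, %d objects, %.2g um/px, frame %d\n",
              nrow(object@labels), ncol(object@labels),
              length(setdiff(unique(as.vector(object@labels)), 0L)),
              object@pixelSize, object@frame))
})
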