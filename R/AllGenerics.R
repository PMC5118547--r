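## Accessor generics and show methods.  Slots are never accessed directly by
## user code; these accessors are the supported surface.

#' @name accessors
#' @title Accessors for photocycle data containers
#' @description Small read-only accessors for the S4 containers: grids,
#'   matrices, fitted quantities and composition values.
#' @param object an object of the documented class.
#' @return the slot value described for each method.
NULL

#' @rdname accessors
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))
#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("deltaA", function(object) standardGeneric("deltaA"))
#' @rdname accessors
#' @export
setGeneric("schemeStates", function(object) standardGeneric("schemeStates"))
#' @rdname accessors
#' @export
setGeneric("schemeEdges", function(object) standardGeneric("schemeEdges"))
#' @rdname accessors
#' @export
setGeneric("excitedFraction",
           function(object) standardGeneric("excitedFraction"))
#' @rdname accessors
#' @export
setGeneric("timeConstants", function(object) standardGeneric("timeConstants"))
#' @rdname accessors
#' @export
setGeneric("amplitudeSpectra",
           function(object) standardGeneric("amplitudeSpectra"))
#' @rdname accessors
#' @export
setGeneric("offsetSpectrum", function(object) standardGeneric("offsetSpectrum"))
#' @rdname accessors
#' @export
setGeneric("residualSS", function(object) standardGeneric("residualSS"))
#' @rdname accessors
#' @export
setGeneric("fitMeta", function(object) standardGeneric("fitMeta"))
#' @rdname accessors
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))
#' @rdname accessors
#' @export
setGeneric("fractionAllTrans",
           function(object) standardGeneric("fractionAllTrans"))
#' @rdname accessors
#' @export
setGeneric("fraction13Cis", function(object) standardGeneric("fraction13Cis"))
#' @rdname accessors
#' @export
setGeneric("fractionSd", function(object) standardGeneric("fractionSd"))
#' @rdname accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setGeneric("assignmentWindows",
           function(object) standardGeneric("assignmentWindows"))
#' @rdname accessors
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))
#' @rdname accessors
#' @export
setGeneric("transportMode", function(object) standardGeneric("transportMode"))
#' @rdname accessors
#' @export
setGeneric("conditionSlopes",
           function(object) standardGeneric("conditionSlopes"))

#' @rdname accessors
setMethod("timePoints", "TransientSurface", function(object) object@time)
#' @rdname accessors
setMethod("timePoints", "PHTrace", function(object) object@time)
#' @rdname accessors
setMethod("timePoints", "Chromatogram", function(object) object@time)
#' @rdname accessors
setMethod("wavelengths", "TransientSurface",
          function(object) object@wavelength)
#' @rdname accessors
setMethod("wavelengths", "Spectrum", function(object) object@wavelength)
#' @rdname accessors
setMethod("wavelengths", "SpeciesSpectra", function(object) object@wavelength)
#' @rdname accessors
setMethod("wavelengths", "GlobalFitResult", function(object) object@wavelength)
#' @rdname accessors
setMethod("deltaA", "TransientSurface", function(object) object@deltaA)
#' @rdname accessors
setMethod("schemeStates", "PhotocycleScheme", function(object) object@states)
#' @rdname accessors
setMethod("schemeEdges", "PhotocycleScheme", function(object) object@edges)
#' @rdname accessors
setMethod("excitedFraction", "PhotocycleScheme",
          function(object) object@excitedFraction)
#' @rdname accessors
setMethod("timeConstants", "GlobalFitResult", function(object) object@tau)
#' @rdname accessors
setMethod("timeConstants", "TraceFitResult", function(object) object@tau)
#' @rdname accessors
setMethod("amplitudeSpectra", "GlobalFitResult", function(object) object@das)
#' @rdname accessors
setMethod("amplitudeSpectra", "TraceFitResult",
          function(object) object@amplitudes)
#' @rdname accessors
setMethod("offsetSpectrum", "GlobalFitResult", function(object) object@offset)
#' @rdname accessors
setMethod("offsetSpectrum", "TraceFitResult", function(object) object@offset)
#' @rdname accessors
setMethod("residualSS", "GlobalFitResult", function(object) object@rss)
#' @rdname accessors
setMethod("residualSS", "TraceFitResult", function(object) object@rss)
#' @rdname accessors
setMethod("fitMeta", "GlobalFitResult", function(object) object@meta)
#' @rdname accessors
setMethod("fitMeta", "TraceFitResult", function(object) object@meta)
#' @rdname accessors
setMethod("absorbance", "Spectrum", function(object) object@absorbance)
#' @rdname accessors
setMethod("fractionAllTrans", "IsomerFractions", function(object) object@fAT)
#' @rdname accessors
setMethod("fraction13Cis", "IsomerFractions",
          function(object) 1 - object@fAT)
#' @rdname accessors
setMethod("fractionSd", "IsomerFractions", function(object) object@sd)
#' @rdname accessors
setMethod("signalValues", "Chromatogram", function(object) object@signal)
#' @rdname accessors
setMethod("assignmentWindows", "Chromatogram",
          function(object) object@windows)
#' @rdname accessors
setMethod("peakTable", "PeakTable", function(object) object@peaks)
#' @rdname accessors
setMethod("transportMode", "TransportCall", function(object) object@mode)
#' @rdname accessors
setMethod("conditionSlopes", "TransportCall", function(object) object@slopes)

## -- show methods ----------------------------------------------------------

.fmtTau <- function(tau) {
  vapply(tau, function(x) {
    if (x < 1e-3) sprintf("%.3g us", x * 1e6)
    else if (x < 1) sprintf("%.3g ms", x * 1e3)
    else sprintf("%.3g s", x)
  }, character(1))
}

setMethod("show", "PhotocycleScheme", function(object) {
  cat(sprintf("PhotocycleScheme with %d states: %s\n",
              length(object@states), paste(object@states, collapse = " -> ")))
  cat(sprintf("  %d edges, excited fraction %.3g\n",
              nrow(object@edges), object@excitedFraction))
  lt <- 1 / object@edges$rate
  cat("  lifetimes:", paste(.fmtTau(sort(lt)), collapse = ", "), "\n")
})

setMethod("show", "TransientSurface", function(object) {
  cat(sprintf(
    "TransientSurface: %d times (%.3g-%.3g s) x %d wavelengths (%g-%g nm)\n",
    length(object@time), min(object@time), max(object@time),
    length(object@wavelength), min(object@wavelength),
    max(object@wavelength)))
  if (!is.na(object@noiseSd))
    cat(sprintf("  synthetic, noise s.d. %.3g (seed %s)\n", object@noiseSd,
                format(object@seed)))
})

setMethod("show", "GlobalFitResult", function(object) {
  cat(sprintf("GlobalFitResult: %d components%s, RSS %.4g\n",
              length(object@tau),
              if (length(object@offset)) " + offset" else "", object@rss))
  cat("  tau:", paste(.fmtTau(object@tau), collapse = ", "), "\n")
  if (length(object@meta$warnings))
    cat("  warnings:", paste(object@meta$warnings, collapse = "; "), "\n")
})

setMethod("show", "TraceFitResult", function(object) {
  cat(sprintf("TraceFitResult: %d components%s, RSS %.4g\n",
              length(object@tau),
              if (!is.na(object@offset)) " + offset" else "", object@rss))
  if (length(object@tau))
    cat("  tau:", paste(.fmtTau(object@tau), collapse = ", "), "\n")
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum%s: %d points, %g-%g nm\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              length(object@wavelength), min(object@wavelength),
              max(object@wavelength)))
})

setMethod("show", "IsomerFractions", function(object) {
  cat(sprintf("IsomerFractions (%s): all-trans %.3f, 13-cis %.3f%s\n",
              object@condition, object@fAT, 1 - object@fAT,
              if (is.na(object@sd)) "" else sprintf(" (s.d. %.3f)", object@sd)))
})

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram: %d points, %g-%g min, %d assignment windows\n",
              length(object@time), min(object@time), max(object@time),
              nrow(object@windows)))
})

setMethod("show", "PeakTable", function(object) {
  cat(sprintf("PeakTable with %d peaks\n", nrow(object@peaks)))
  if (nrow(object@peaks)) print(object@peaks, row.names = FALSE)
})

setMethod("show", "PHTrace", function(object) {
  lw <- if (is.na(object@lightOn)) "dark-only"
        else sprintf("light %g-%g s", object@lightOn, object@lightOff)
  cat(sprintf("PHTrace '%s': %d points, %s, salt %s, CCCP %s\n",
              object@sample, length(object@time), lw, object@salt,
              object@cccp))
})

setMethod("show", "ExpressionResult", function(object) {
  cat(sprintf(
    "ExpressionResult: epsilon %.0f M-1 cm-1, amount %.3g mol\n",
    object@epsilon, object@amount))
})

setMethod("show", "TransportCall", function(object) {
  cat(sprintf("TransportCall: %s\n", object@mode))
  print(object@slopes, row.names = FALSE)
  if (!is.na(object@activity))
    cat(sprintf("  normalized activity: %.4g pH s-1 mol-1\n",
                object@activity))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat("ScenarioConfig\n")
  cat("  lifetimes:", paste(.fmtTau(object@tau), collapse = ", "), "\n")
  cat(sprintf("  fractions: dark %.2f / light %.2f all-trans; seed %d\n",
              object@fDark, object@fLight, object@seed))
})
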