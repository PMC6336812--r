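#' @rdname ActivityTrack
#' @aliases animalId,ActivityTrack-method
setMethod("animalId", "ActivityTrack", function(x) x@animalId)

#' @rdname ActivityTrack
setMethod("genotype", "ActivityTrack", function(x) x@genotype)

#' @rdname ActivityTrack
setMethod("distances", "ActivityTrack", function(x) x@distances)

#' @rdname ActivityTrack
setMethod("binWidth", "ActivityTrack", function(x) x@binWidth)

#' @rdname ActivityTrack
setMethod("schedule", "ActivityTrack", function(x) x@schedule)

#' Duration of a track in seconds
#' @param x an [ActivityTrack-class].
#' @return numeric scalar, seconds.
#' @export
trackDuration <- function(x) length(x@distances) * x@binWidth

#' Bin start times of a track, in seconds after light onset
#' @param x an [ActivityTrack-class].
#' @return numeric vector, one start time per bin.
#' @export
binStarts <- function(x) x@t0 + (seq_along(x@distances) - 1) * x@binWidth

#' @rdname CellTrace
setMethod("animalId", "CellTrace", function(x) x@cellId)

#' @rdname CellTrace
setMethod("sampleTimes", "CellTrace", function(x) x@times)

#' @rdname CellTrace
setMethod("intensities", "CellTrace", function(x) x@intensities)

#' @rdname CellTrace
setMethod("condition", "CellTrace", function(x) x@condition)

#' @rdname ExpressionCourse
#' @param x an `ExpressionCourse`.
setMethod("sampleTimes", "ExpressionCourse", function(x) x@times)

#' @rdname ExpressionCourse
setMethod("intensities", "ExpressionCourse", function(x) x@values)

#' @rdname BoutTable
setMethod("boutData", "BoutTable", function(x) x@bouts)

#' @rdname CosinorFit
setMethod("mesor", "CosinorFit", function(x) x@mesor)

#' @rdname CosinorFit
setMethod("amplitude", "CosinorFit", function(x) x@amplitude)

#' @rdname CosinorFit
setMethod("acrophase", "CosinorFit", function(x) x@acrophase)

#' @rdname CircularSummary
setMethod("resultantLength", "CircularSummary", function(x) x@R)

#' @rdname CircularSummary
setMethod("meanPhase", "CircularSummary", function(x) x@meanPhase)

#' @rdname CircularSummary
setMethod("rayleighP", "CircularSummary", function(x) x@rayleighP)

setMethod("show", "LightSchedule", function(object) {
  cat(sprintf("LightSchedule '%s' with %d light interval(s)\n",
              object@label, nrow(object@intervals)))
})

setMethod("show", "ActivityTrack", function(object) {
  cat(sprintf(
    "ActivityTrack '%s' (%s): %d bins of %g s (%.2f days), schedule %s\n",
    object@animalId, object@genotype, length(object@distances),
    object@binWidth, trackDuration(object) / 86400, object@schedule@label))
})

setMethod("show", "CellTrace", function(object) {
  cat(sprintf("CellTrace '%s' (%s): %d samples over %.1f h\n",
              object@cellId, object@condition, length(object@times),
              diff(range(object@times))))
})

setMethod("show", "ExpressionCourse", function(object) {
  cat(sprintf("ExpressionCourse '%s': %d timepoints over %.1f h\n",
              object@gene, length(object@times), max(object@times)))
})

setMethod("show", "BoutTable", function(object) {
  b <- object@bouts
  cat(sprintf("BoutTable for '%s': %d bouts (%d active, %d immobile)\n",
              object@trackRef, nrow(b), sum(b$state == "active"),
              sum(b$state == "immobile")))
})

setMethod("show", "PeriodogramResult", function(object) {
  cat(sprintf(
    "PeriodogramResult (%s): peak %.2f h, power %.1f (threshold %.1f)\n",
    object@method, object@peakPeriod, object@peakPower,
    object@threshold[which.max(object@power)]))
})

setMethod("show", "RhythmCall", function(object) {
  cat(sprintf("RhythmCall '%s': %s (peak %.2f h, excess %.1f)\n",
              object@animalId,
              if (object@isRhythmic) "rhythmic" else "arrhythmic",
              object@peakPeriod, object@excess))
})

setMethod("show", "CosinorFit", function(object) {
  cat(sprintf(
    "CosinorFit: mesor %.3g, amplitude %.3g, acrophase %.2f h (tau %g h), p = %.3g\n",
    object@mesor, object@amplitude, object@acrophase, object@period,
    object@pValue))
})

setMethod("show", "CircularSummary", function(object) {
  cat(sprintf(
    "CircularSummary: n = %d, mean phase %.2f rad, R = %.3f, Rayleigh p = %.3g\n",
    object@n, object@meanPhase, object@R, object@rayleighP))
})

setMethod("show", "GenotypePreset", function(object) {
  cat(sprintf(
    "GenotypePreset '%s': rest %.0f s / active %.2f h, mod depth 12h = %.2f\n",
    object@name, object@meanRestBout, object@meanActivePeriod,
    object@modDepth[["pulse_12h"]]))
})

setMethod("show", "ThresholdEstimate", function(object) {
  cat(sprintf("ThresholdEstimate: %.1f s (improvement %.1f%%, %s)\n",
              object@threshold, 100 * object@fitQuality,
              if (object@valid) "valid" else "not valid"))
})
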