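#' Construct a light schedule
#'
#' @param label schedule label.  `"pulse_3h"` and `"pulse_12h"` create a
#'   single light interval of that length starting at recording time 0;
#'   `"DD"` creates constant darkness.  `"custom"` requires `intervals`.
#' @param intervals optional two-column matrix (`on_s`, `off_s`) in seconds
#'   from recording start; overrides the preset interval.
#' @return a [LightSchedule-class] object.
#' @examples
#' LightSchedule("pulse_12h")
#' @export
LightSchedule <- function(label = c("DD", "pulse_3h", "pulse_12h", "custom"),
                          intervals = NULL) {
  label <- match.arg(label)
  if (is.null(intervals)) {
    intervals <- switch(label,
      DD        = matrix(numeric(0), ncol = 2),
      pulse_3h  = matrix(c(0, 3 * 3600), ncol = 2),
      pulse_12h = matrix(c(0, 12 * 3600), ncol = 2),
      custom    = stop("a custom schedule requires explicit intervals"))
  }
  if (!is.matrix(intervals)) intervals <- matrix(intervals, ncol = 2)
  colnames(intervals) <- c("on_s", "off_s")
  new("LightSchedule", intervals = intervals, label = label)
}

#' Seconds of light-pulse history at the start of a schedule
#'
#' Returns the end (s) of the initial light interval, or 0 for DD.
#' @param x a [LightSchedule-class].
#' @return numeric scalar, seconds.
#' @export
pulseEnd <- function(x) {
  stopifnot(is(x, "LightSchedule"))
  if (nrow(x@intervals) == 0) 0 else unname(x@intervals[1, 2])
}

#' Construct an activity track
#'
#' @param distances numeric vector of distance moved per bin (mm).
#' @param binWidth bin width in seconds; 1 for bout analysis.
#' @param animalId animal identifier.
#' @param genotype genotype label.
#' @param t0 recording start in seconds relative to light onset.
#' @param schedule a [LightSchedule-class]; default DD.
#' @return an [ActivityTrack-class] object.
#' @examples
#' ActivityTrack(c(0, 0.4, 0), animalId = "fish1")
#' @export
ActivityTrack <- function(distances, binWidth = 1, animalId = "animal",
                          genotype = "WT", t0 = 0,
                          schedule = LightSchedule("DD")) {
  new("ActivityTrack", animalId = as.character(animalId),
      genotype = genotype, binWidth = as.numeric(binWidth),
      t0 = as.numeric(t0), distances = as.numeric(distances),
      schedule = schedule)
}

#' Construct a single-cell trace
#'
#' @param times sample times in hours, strictly increasing.
#' @param intensities bioluminescence values.
#' @param cellId cell identifier.
#' @param condition `"dark"` or `"light_12h"`.
#' @return a [CellTrace-class] object.
#' @export
CellTrace <- function(times, intensities, cellId = "cell",
                      condition = c("dark", "light_12h")) {
  condition <- match.arg(condition)
  new("CellTrace", cellId = as.character(cellId), condition = condition,
      times = as.numeric(times), intensities = as.numeric(intensities))
}

#' Construct a relative expression course
#'
#' Values are divided by the value at the earliest timepoint so that the
#' course starts at 1, the convention for light-induction time courses.
#'
#' @param times hours after light onset, strictly increasing.
#' @param values raw (positive) expression values.
#' @param gene gene name.
#' @param normalize divide by the first value (default `TRUE`).
#' @return an [ExpressionCourse-class] object.
#' @export
ExpressionCourse <- function(times, values, gene = "gene", normalize = TRUE) {
  values <- as.numeric(values)
  if (normalize) {
    if (values[1] <= 0) stop("value at the earliest timepoint must be positive")
    values <- values / values[1]
  }
  new("ExpressionCourse", gene = as.character(gene),
      times = as.numeric(times), values = values)
}

#' Construct an analysis configuration
#'
#' @param movementEpsilon immobility threshold in mm (default 0).
#' @param restThreshold rest-bout threshold in seconds (default 60).
#' @param periodRange periodogram scan range in hours (default 16-32).
#' @param alpha significance level (default 0.05).
#' @param activityWindow `c(start_s, end_s)` after light onset, or `NA` to
#'   use each track's post-pulse epoch.
#' @param seed integer seed recorded in the run manifest.
#' @return an [AnalysisConfig-class] object.
#' @export
AnalysisConfig <- function(movementEpsilon = 0, restThreshold = 60,
                           periodRange = c(16, 32), alpha = 0.05,
                           activityWindow = NA_real_, seed = 1L) {
  new("AnalysisConfig", movementEpsilon = movementEpsilon,
      restThreshold = restThreshold, periodRange = periodRange,
      alpha = alpha, activityWindow = as.numeric(activityWindow),
      seed = as.integer(seed))
}
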