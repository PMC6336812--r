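#' @import methods
NULL

GENOTYPES <- c("WT", "Cry1aKO", "Per2KO", "DKO", "TKO", "custom")
SCHEDULE_LABELS <- c("DD", "pulse_3h", "pulse_12h", "custom")
TRACE_CONDITIONS <- c("dark", "light_12h")

#' Light schedule of a recording
#'
#' Ordered light intervals relative to the start of the recording, in
#' seconds.  A `"DD"` schedule (constant darkness) has no intervals; the
#' pulse presets carry a single light interval starting at recording time 0,
#' which is the convention used throughout: recordings start at light onset
#' and circadian phase is expressed in hours after light onset.
#'
#' @slot intervals two-column numeric matrix (`on_s`, `off_s`), possibly
#'   zero-row, strictly increasing and non-overlapping.
#' @slot label one of `"DD"`, `"pulse_3h"`, `"pulse_12h"`, `"custom"`.
#' @exportClass LightSchedule
setClass("LightSchedule",
  representation(intervals = "matrix", label = "character"))

setValidity("LightSchedule", function(object) {
  iv <- object@intervals
  if (!is.numeric(iv) || ncol(iv) != 2)
    return("intervals must be a two-column numeric matrix")
  if (length(object@label) != 1 || !object@label %in% SCHEDULE_LABELS)
    return(sprintf("label must be one of %s",
                   paste(SCHEDULE_LABELS, collapse = ", ")))
  if (object@label == "DD" && nrow(iv) > 0)
    return("a DD schedule has no light intervals")
  if (nrow(iv) > 0) {
    if (any(!is.finite(iv))) return("intervals must be finite")
    if (any(iv[, 2] <= iv[, 1])) return("light-off must follow light-on")
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      return("light intervals must be non-overlapping and increasing")
  }
  TRUE
})

#' One animal's locomotor track
#'
#' Distance moved per fixed time-bin for a single larva, together with
#' genotype and light-schedule metadata.  Bout analysis requires 1-s bins;
#' actograms and periodograms use 10-min (600-s) re-binned tracks.
#'
#' @slot animalId single character identifier.
#' @slot genotype one of `"WT"`, `"Cry1aKO"`, `"Per2KO"`, `"DKO"`, `"TKO"`,
#'   `"custom"`.
#' @slot binWidth bin width in seconds (> 0).
#' @slot t0 recording start in seconds relative to light onset; bin `i`
#'   covers time-after-light-onset `[t0 + (i-1)*binWidth, t0 + i*binWidth)`.
#' @slot distances non-negative finite numeric, one value per bin (mm).
#' @slot schedule a [LightSchedule-class] object.
#' @exportClass ActivityTrack
setClass("ActivityTrack",
  representation(animalId = "character", genotype = "character",
                 binWidth = "numeric", t0 = "numeric",
                 distances = "numeric", schedule = "LightSchedule"))

setValidity("ActivityTrack", function(object) {
  if (length(object@animalId) != 1) return("animalId must be length 1")
  if (!object@genotype %in% GENOTYPES)
    return(sprintf("genotype must be one of %s",
                   paste(GENOTYPES, collapse = ", ")))
  if (length(object@binWidth) != 1 || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    return("binWidth must be a single positive number")
  if (length(object@distances) < 1) return("track must have at least one bin")
  if (any(!is.finite(object@distances)))
    return("all distances must be finite")
  if (any(object@distances < 0)) return("distances must be non-negative")
  TRUE
})

#' Single-cell bioluminescence trace
#'
#' @slot cellId single character identifier.
#' @slot condition `"dark"` (free-running, never light-exposed) or
#'   `"light_12h"` (12-h light pulse before recording).
#' @slot times sample times in hours, strictly increasing.
#' @slot intensities finite bioluminescence values (arbitrary units), same
#'   length as `times`.
#' @exportClass CellTrace
setClass("CellTrace",
  representation(cellId = "character", condition = "character",
                 times = "numeric", intensities = "numeric"))

setValidity("CellTrace", function(object) {
  if (length(object@cellId) != 1) return("cellId must be length 1")
  if (!object@condition %in% TRACE_CONDITIONS)
    return(sprintf("condition must be one of %s",
                   paste(TRACE_CONDITIONS, collapse = ", ")))
  if (length(object@times) != length(object@intensities))
    return("times and intensities must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(!is.finite(object@intensities)))
    return("intensities must be finite")
  TRUE
})

#' Relative gene-expression time course
#'
#' Expression after light onset, normalized so the value at the earliest
#' timepoint equals 1.
#'
#' @slot gene gene name.
#' @slot times sample times in hours after light onset, strictly increasing.
#' @slot values positive relative expression; first value is 1.
#' @exportClass ExpressionCourse
setClass("ExpressionCourse",
  representation(gene = "character", times = "numeric", values = "numeric"))

setValidity("ExpressionCourse", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    return("values must be finite and positive")
  if (abs(object@values[1] - 1) > 1e-8)
    return("value at the earliest timepoint must be normalized to 1")
  TRUE
})

#' Analysis configuration
#'
#' @slot movementEpsilon distance threshold in mm below which a 1-s bin is
#'   immobile; default 0 ("without a detectable movement" is literally zero).
#' @slot restThreshold minimum immobile-bout duration in seconds that
#'   qualifies as sleep-like rest; default 60.
#' @slot periodRange periodogram scan range in hours, default `c(16, 32)`.
#' @slot alpha significance level, default 0.05.
#' @slot activityWindow analysis window `c(start_s, end_s)` in seconds after
#'   light onset, or `NA` to use the post-pulse epoch of each track.
#' @slot seed integer RNG seed recorded in run manifests.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(movementEpsilon = "numeric", restThreshold = "numeric",
                 periodRange = "numeric", alpha = "numeric",
                 activityWindow = "numeric", seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  if (object@movementEpsilon < 0) return("movementEpsilon must be >= 0")
  if (object@restThreshold <= 0) return("restThreshold must be positive")
  if (length(object@periodRange) != 2 ||
      object@periodRange[1] >= object@periodRange[2])
    return("periodRange must be c(min, max) with min < max")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  if (!all(is.na(object@activityWindow)) &&
      (length(object@activityWindow) != 2 ||
       object@activityWindow[1] >= object@activityWindow[2]))
    return("activityWindow must be c(start, end) with start < end, or NA")
  TRUE
})

#' Alternating bout segmentation of a track
#'
#' Maximal runs of consecutive same-state 1-s bins: active bouts (with
#' movement) strictly alternating with immobile bouts (no movement).
#'
#' @slot bouts data.frame with columns `state` ("active"/"immobile"),
#'   `start_s`, `duration_s`, `distance_mm`.
#' @slot trackRef animal id of the source track.
#' @slot binWidth source bin width in seconds.
#' @exportClass BoutTable
setClass("BoutTable",
  representation(bouts = "data.frame", trackRef = "character",
                 binWidth = "numeric"))

setValidity("BoutTable", function(object) {
  b <- object@bouts
  need <- c("state", "start_s", "duration_s", "distance_mm")
  if (!all(need %in% names(b)))
    return(sprintf("bouts must have columns %s", paste(need, collapse = ", ")))
  if (nrow(b) == 0) return("bouts must have at least one row")
  if (!all(b$state %in% c("active", "immobile")))
    return("state must be 'active' or 'immobile'")
  if (nrow(b) > 1 && any(b$state[-1] == b$state[-nrow(b)]))
    return("bout states must strictly alternate")
  if (any(b$duration_s < object@binWidth))
    return("bout durations must be at least one bin width")
  if (any(b$distance_mm[b$state == "immobile"] != 0))
    return("immobile bouts must have zero distance")
  TRUE
})

#' Empirical cumulative distribution of bout lengths
#'
#' @slot lengths sorted unique bout lengths in seconds.
#' @slot cumProb cumulative probability at each length; non-decreasing,
#'   final value 1.
#' @slot state bout state the curve summarizes.
#' @slot n number of pooled bouts.
#' @exportClass EcdfCurve
setClass("EcdfCurve",
  representation(lengths = "numeric", cumProb = "numeric",
                 state = "character", n = "integer"))

setValidity("EcdfCurve", function(object) {
  if (length(object@lengths) != length(object@cumProb))
    return("lengths and cumProb must have equal length")
  if (is.unsorted(object@lengths, strictly = TRUE))
    return("lengths must be sorted and unique")
  if (any(diff(object@cumProb) < 0)) return("cumProb must be non-decreasing")
  if (abs(object@cumProb[length(object@cumProb)] - 1) > 1e-12)
    return("final cumulative probability must be 1")
  TRUE
})

#' Rest-threshold changepoint estimate
#'
#' Breakpoint of a two-segment continuous broken-line fit to the log-log
#' survival curve of immobile bout lengths.
#'
#' @slot threshold estimated changepoint in seconds.
#' @slot fitQuality relative residual improvement of the two-segment fit
#'   over a single line (1 - RSS2/RSS1).
#' @slot valid `TRUE` when the improvement reaches the 20% requirement.
#' @exportClass ThresholdEstimate
setClass("ThresholdEstimate",
  representation(threshold = "numeric", fitQuality = "numeric",
                 valid = "logical"))

setValidity("ThresholdEstimate", function(object) {
  if (isTRUE(object@valid) && object@threshold <= 0)
    return("a valid estimate must have a positive threshold")
  TRUE
})

#' Double-plottable actogram matrix
#'
#' @slot activity matrix with one row per 24-h day; 144 columns of 10-min
#'   bins, or 288 when doubled (day d followed by day d+1).
#' @slot doubled logical, 48-h double plotting.
#' @slot binWidth bin width in seconds.
#' @exportClass Actogram
setClass("Actogram",
  representation(activity = "matrix", doubled = "logical",
                 binWidth = "numeric"))

setValidity("Actogram", function(object) {
  perDay <- 86400 / object@binWidth
  want <- if (object@doubled) 2 * perDay else perDay
  if (ncol(object@activity) != want)
    return(sprintf("actogram rows must have %d columns", want))
  if (any(object@activity < 0)) return("activity must be non-negative")
  TRUE
})

#' Periodogram of a binned activity track
#'
#' @slot periods scanned periods in hours.
#' @slot power periodogram statistic at each period (chi-square Qp, or
#'   Lomb-Scargle normalized power).
#' @slot threshold significance curve at level alpha, Bonferroni-corrected
#'   across the scanned periods.
#' @slot peakPeriod period (h) of the maximum statistic.
#' @slot peakPower statistic at the peak.
#' @slot alpha significance level.
#' @slot method `"chisq"` or `"lombscargle"`.
#' @exportClass PeriodogramResult
setClass("PeriodogramResult",
  representation(periods = "numeric", power = "numeric",
                 threshold = "numeric", peakPeriod = "numeric",
                 peakPower = "numeric", alpha = "numeric",
                 method = "character"))

setValidity("PeriodogramResult", function(object) {
  if (length(object@periods) != length(object@power) ||
      length(object@periods) != length(object@threshold))
    return("periods, power and threshold must have equal length")
  if (any(object@power < 0)) return("power must be non-negative")
  TRUE
})

#' Rhythmicity call for one animal
#'
#' @slot animalId animal identifier.
#' @slot isRhythmic `TRUE` when the periodogram peak exceeds its
#'   significance threshold and lies within the circadian band.
#' @slot peakPeriod peak period in hours.
#' @slot excess peak statistic minus threshold at the peak.
#' @exportClass RhythmCall
setClass("RhythmCall",
  representation(animalId = "character", isRhythmic = "logical",
                 peakPeriod = "numeric", excess = "numeric"))

#' Single-component cosinor fit
#'
#' Least-squares fit of `y(t) = M + A * cos(2*pi*(t - phi)/tau)`.
#'
#' @slot mesor rhythm-adjusted mean M.
#' @slot amplitude A >= 0.
#' @slot acrophase phi in hours within `[0, tau)`: time after light onset at
#'   which the fitted cosine peaks.
#' @slot period fitted period tau in hours.
#' @slot pValue zero-amplitude F-test p-value (df 2, n - 3).
#' @slot rss residual sum of squares.
#' @slot n number of samples.
#' @exportClass CosinorFit
setClass("CosinorFit",
  representation(mesor = "numeric", amplitude = "numeric",
                 acrophase = "numeric", period = "numeric",
                 pValue = "numeric", rss = "numeric", n = "integer"))

setValidity("CosinorFit", function(object) {
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (object@acrophase < 0 || object@acrophase >= object@period)
    return("acrophase must lie in [0, period)")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must be in [0, 1]")
  TRUE
})

#' Circular summary of a phase sample
#'
#' @slot n number of phases.
#' @slot meanPhase circular mean phase in radians, `[0, 2*pi)`.
#' @slot R resultant length in `[0, 1]`; 1 is perfect synchrony.
#' @slot rayleighP Rayleigh uniformity test p-value (Zar's approximation).
#' @slot histogram counts per angular bin.
#' @slot breaks bin edges in radians, from 0 to `2*pi`.
#' @exportClass CircularSummary
setClass("CircularSummary",
  representation(n = "integer", meanPhase = "numeric", R = "numeric",
                 rayleighP = "numeric", histogram = "integer",
                 breaks = "numeric"))

setValidity("CircularSummary", function(object) {
  if (object@R < 0 || object@R > 1 + 1e-12)
    return("resultant length must be in [0, 1]")
  if (sum(object@histogram) != object@n)
    return("histogram counts must sum to n")
  TRUE
})

#' Genotype preset for the behavioral simulator
#'
#' Parameters of the alternating-renewal locomotor model, calibrated so the
#' expected resting time per day under a 12-h light pulse matches the
#' genotype contrasts the behavioral assay quantifies (about 7.8 h for WT
#' and about 20.5-20.6 h for the clock double/triple knockouts), and so the
#' circadian modulation depth reproduces the light-history ordering of
#' rhythm formation across genotypes.
#'
#' @slot name `"WT"`, `"DKO"` or `"TKO"`.
#' @slot meanRestBout mean rest-bout duration in seconds (lognormal).
#' @slot meanActivePeriod mean active-period duration in hours (lognormal).
#' @slot sdlog lognormal log-sd shared by both duration distributions.
#' @slot shortPauseRate short (< 60 s) pause initiations per minute within
#'   active periods.
#' @slot meanShortPause mean short-pause duration in seconds (exponential).
#' @slot distMean mean distance per moving second in mm.
#' @slot distShape gamma shape of per-second distances.
#' @slot modDepth named numeric `c(DD=, pulse_3h=, pulse_12h=)`: depth in
#'   `[0, 1]` of the circadian modulation of rest initiation after the
#'   light pulse.
#' @slot phi0 acrophase (hours after light onset) of rest initiation;
#'   default mid subjective night.
#' @exportClass GenotypePreset
setClass("GenotypePreset",
  representation(name = "character", meanRestBout = "numeric",
                 meanActivePeriod = "numeric", sdlog = "numeric",
                 shortPauseRate = "numeric", meanShortPause = "numeric",
                 distMean = "numeric", distShape = "numeric",
                 modDepth = "numeric", phi0 = "numeric"))

setValidity("GenotypePreset", function(object) {
  pos <- c(object@meanRestBout, object@meanActivePeriod, object@sdlog,
           object@shortPauseRate, object@meanShortPause, object@distMean,
           object@distShape)
  if (any(!is.finite(pos)) || any(pos <= 0))
    return("all rate/scale parameters must be positive")
  if (!all(c("DD", "pulse_3h", "pulse_12h") %in% names(object@modDepth)))
    return("modDepth must name DD, pulse_3h and pulse_12h")
  if (any(object@modDepth < 0) || any(object@modDepth > 1))
    return("modulation depths must lie in [0, 1]")
  TRUE
})

#' Parameters of the damped single-cell oscillator simulator
#'
#' @slot period oscillation period in hours (about 24).
#' @slot amplitude oscillation amplitude (> 0, arbitrary units).
#' @slot damping fractional amplitude loss per 24 h, in `[0, 1)`.
#' @slot noiseSd additive Gaussian noise sd.
#' @slot trendSlope fractional baseline drift per hour.
#' @slot phaseMode `"uniform_random"` (desynchronized, dark) or `"common"`
#'   (light-synchronized).
#' @slot commonPhaseSd sd in hours of the wrapped-normal phase spread in
#'   common mode.
#' @slot phi0 common acrophase in hours after light onset.
#' @slot baseline baseline intensity.
#' @exportClass OscillatorParams
setClass("OscillatorParams",
  representation(period = "numeric", amplitude = "numeric",
                 damping = "numeric", noiseSd = "numeric",
                 trendSlope = "numeric", phaseMode = "character",
                 commonPhaseSd = "numeric", phi0 = "numeric",
                 baseline = "numeric"))

setValidity("OscillatorParams", function(object) {
  if (object@amplitude <= 0) return("amplitude must be positive")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@damping < 0 || object@damping >= 1)
    return("damping must be in [0, 1)")
  if (!object@phaseMode %in% c("uniform_random", "common"))
    return("phaseMode must be 'uniform_random' or 'common'")
  TRUE
})
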