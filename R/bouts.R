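#' Classify 1-s bins as active or immobile
#'
#' A bin is active when its distance exceeds the movement threshold
#' `epsilon` (default 0 mm: any detectable movement counts as activity, the
#' literal reading of immobility as zero recorded distance; raise `epsilon`
#' to model a tracker noise floor).
#'
#' @param track an [ActivityTrack-class] with 1-s bins.
#' @param epsilon movement threshold in mm, >= 0.
#' @return logical vector, `TRUE` for active bins.
#' @examples
#' classifyBins(ActivityTrack(c(0, 0.2, 0)))
#' @export
classifyBins <- function(track, epsilon = 0) {
  stopifnot(is(track, "ActivityTrack"), epsilon >= 0)
  if (track@binWidth != 1)
    stop("bout analysis is defined on 1-s bins; rebin or retrack the data")
  track@distances > epsilon
}

#' Segment a binary activity sequence into alternating bouts
#'
#' Maximal runs of consecutive same-state bins become bouts; per-bout
#' distance is the sum of its bins' distances (zero for immobile bouts).
#'
#' @param states logical vector, `TRUE` = active (from [classifyBins()]).
#' @param distances per-bin distances in mm, same length as `states`.
#' @param binWidth bin width in seconds.
#' @param trackRef animal id carried into the result.
#' @return a [BoutTable-class]; durations partition the track exactly.
#' @export
segmentBouts <- function(states, distances = numeric(length(states)),
                         binWidth = 1, trackRef = "") {
  stopifnot(length(states) >= 1, length(distances) == length(states))
  r <- rle(as.logical(states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dist <- vapply(seq_along(starts), function(i)
    sum(distances[starts[i]:ends[i]]), numeric(1))
  dist[!r$values] <- 0
  b <- data.frame(
    state = ifelse(r$values, "active", "immobile"),
    start_s = (starts - 1) * binWidth,
    duration_s = r$lengths * binWidth,
    distance_mm = dist,
    stringsAsFactors = FALSE)
  new("BoutTable", bouts = b, trackRef = as.character(trackRef),
      binWidth = binWidth)
}

#' Segment a track into bouts
#'
#' Convenience wrapper: [classifyBins()] then [segmentBouts()].
#'
#' @param track an [ActivityTrack-class] with 1-s bins.
#' @param epsilon movement threshold in mm.
#' @return a [BoutTable-class].
#' @export
trackBouts <- function(track, epsilon = 0) {
  segmentBouts(classifyBins(track, epsilon), distances(track),
               binWidth = binWidth(track), trackRef = animalId(track))
}

#' Empirical cumulative distribution of bout lengths
#'
#' Pooled over whatever bouts the caller supplies (pooling across animals of
#' one genotype is the caller's concern).
#'
#' @param lengths bout lengths in seconds, at least one.
#' @param state label recorded on the curve (`"immobile"` or `"active"`).
#' @return an [EcdfCurve-class].
#' @examples
#' boutEcdf(c(10, 10, 20))
#' @export
boutEcdf <- function(lengths, state = "immobile") {
  if (length(lengths) < 1) stop("at least one bout length is required")
  stopifnot(all(is.finite(lengths)), all(lengths > 0))
  u <- sort(unique(lengths))
  cp <- cumsum(tabulate(match(sort(lengths), u))) / length(lengths)
  new("EcdfCurve", lengths = u, cumProb = cp, state = state,
      n = length(lengths))
}

#' Estimate the rest threshold from an immobile-bout length distribution
#'
#' Fits a two-segment continuous broken line to `log10(1 - cumProb)` versus
#' `log10(length)` (the log-log survival curve), searching candidate
#' breakpoints exhaustively at the observed lengths and minimizing total
#' squared residual.  The survival curve of pooled immobile bouts kinks
#' where short within-activity pauses give way to long sleep-like rests;
#' the breakpoint estimates that changeover.  The estimate is flagged not
#' valid when the two-segment fit improves the residual by less than
#' `minImprovement` over a single line (no detectable kink, e.g. a single
#' exponential).
#'
#' @param ecdf an [EcdfCurve-class] of immobile bout lengths with at least
#'   50 distinct lengths spanning at least one decade.
#' @param minImprovement required relative residual improvement (default
#'   0.2).
#' @param minTail smallest number of exceedances a survival point must rest
#'   on to enter the fit (default 10): the empirical log-survival of the
#'   few largest bouts plunges below the underlying curve and would fake a
#'   changepoint.
#' @param minSlopeChange smallest absolute difference between the two
#'   segment slopes for a valid changepoint (default 0.25).  Empirical
#'   survival curves wander around their expectation in a correlated way,
#'   so a two-segment fit improves the residual even on single-family
#'   samples; a genuine regime change additionally shows distinctly
#'   different exponents on the two sides.
#' @return a [ThresholdEstimate-class].
#' @export
estimateRestThreshold <- function(ecdf, minImprovement = 0.2,
                                  minTail = 10, minSlopeChange = 0.25) {
  stopifnot(is(ecdf, "EcdfCurve"))
  surv <- 1 - ecdf@cumProb
  keep <- surv >= minTail / ecdf@n    # also excludes survival = 0
  x <- log10(ecdf@lengths[keep])
  y <- log10(surv[keep])
  if (length(x) < 50 || (max(x) - min(x)) < 1)
    stop(paste("need >= 50 distinct immobile bout lengths spanning >= one",
               "decade; fall back to the conventional 60 s threshold"))
  fit1 <- stats::lm.fit(cbind(1, x), y)
  rss1 <- sum(fit1$residuals^2)
  # continuous broken line: y = a + s1*min(x-b,0) + s2*max(x-b,0)
  cand <- x[x > min(x) & x < max(x)]
  best <- list(rss = Inf, b = NA_real_, dslope = 0)
  for (b in cand) {
    X <- cbind(1, pmin(x - b, 0), pmax(x - b, 0))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (rss < best$rss)
      best <- list(rss = rss, b = b,
                   dslope = abs(f$coefficients[3] - f$coefficients[2]))
  }
  improvement <- if (rss1 > 0) 1 - best$rss / rss1 else 0
  new("ThresholdEstimate", threshold = 10^best$b,
      fitQuality = improvement,
      valid = improvement >= minImprovement &&
        best$dslope >= minSlopeChange)
}

.clip <- function(a, b, lo, hi) c(max(a, lo), min(b, hi))

#' Rest/activity architecture statistics for one animal
#'
#' Applies the sleep-like rest definition: an immobile bout of
#' `restThreshold` (default 60) seconds or longer is a rest bout; active
#' periods are the maximal intervals between rest bouts, absorbing shorter
#' immobile pauses.  Within the analysis window:
#' * `restingTime_h_per_day`: summed rest-bout time (clipped to the
#'   window), scaled to hours per 24-h day;
#' * `nActiveRestCycles`: number of rest bouts lying fully inside the
#'   window (one rest terminates one active-rest cycle);
#' * `meanActivePeriod_h` and `meanDistancePerActivePeriod_mm`: averaged
#'   over active periods fully inside the window.  Periods censored by the
#'   window edge (their underlying extent crosses the window boundary) are
#'   excluded from the means, but their in-window time still counts toward
#'   the rest/active partition.
#'
#' @param bouts a [BoutTable-class].
#' @param restThreshold rest-bout threshold in seconds.
#' @param window `c(start_s, end_s)` within the track extent; default the
#'   whole track.
#' @return one-row data.frame with the four statistics plus `animalId`;
#'   means are `NA` when no complete active period exists.
#' @export
computeRestStats <- function(bouts, restThreshold = 60, window = NULL) {
  stopifnot(is(bouts, "BoutTable"), restThreshold > 0)
  b <- bouts@bouts
  trackStart <- b$start_s[1]
  trackEnd <- b$start_s[nrow(b)] + b$duration_s[nrow(b)]
  if (is.null(window)) window <- c(trackStart, trackEnd)
  if (window[1] < trackStart - 1e-9 || window[2] > trackEnd + 1e-9)
    stop("window must lie within the track extent")
  winLen <- window[2] - window[1]
  if (winLen < restThreshold)
    stop("analysis window must be at least one rest threshold long")

  isRest <- b$state == "immobile" & b$duration_s >= restThreshold
  rs <- b$start_s[isRest]
  re <- rs + b$duration_s[isRest]
  # keep rest bouts overlapping the window
  keep <- re > window[1] & rs < window[2]
  rs <- rs[keep]; re <- re[keep]
  restClipped <- pmin(re, window[2]) - pmax(rs, window[1])
  restingTime <- sum(restClipped)
  fullyInside <- rs >= window[1] - 1e-9 & re <= window[2] + 1e-9
  nCycles <- sum(fullyInside)

  # active periods: complement of rest bouts over the whole track, then
  # assessed against the window
  bounds <- c(trackStart, as.vector(rbind(rs0 <- b$start_s[isRest],
                                          rs0 + b$duration_s[isRest])),
              trackEnd)
  apStart <- bounds[seq(1, length(bounds) - 1, by = 2)]
  apEnd <- bounds[seq(2, length(bounds), by = 2)]
  nonEmpty <- apEnd > apStart + 1e-9
  apStart <- apStart[nonEmpty]; apEnd <- apEnd[nonEmpty]
  overlaps <- apEnd > window[1] & apStart < window[2]
  apStart <- apStart[overlaps]; apEnd <- apEnd[overlaps]
  complete <- apStart >= window[1] - 1e-9 & apEnd <= window[2] + 1e-9

  apLen <- apEnd[complete] - apStart[complete]
  apDist <- vapply(which(complete), function(i) {
    act <- b$state == "active"
    inP <- b$start_s >= apStart[i] - 1e-9 &
           (b$start_s + b$duration_s) <= apEnd[i] + 1e-9
    sum(b$distance_mm[act & inP])
  }, numeric(1))

  data.frame(
    animalId = bouts@trackRef,
    restingTime_h_per_day = restingTime / winLen * 24,
    nActiveRestCycles = nCycles,
    meanDistancePerActivePeriod_mm =
      if (length(apDist)) mean(apDist) else NA_real_,
    meanActivePeriod_h =
      if (length(apLen)) mean(apLen) / 3600 else NA_real_,
    stringsAsFactors = FALSE)
}

#' Total distance moved within a time window
#'
#' Sums per-bin distances over a window expressed in days after light
#' onset; invariant to re-binning (a bin counts when its start time falls
#' inside the window).
#'
#' @param track an [ActivityTrack-class].
#' @param windowDays `c(start_day, end_day)` after light onset.
#' @return total distance in mm.
#' @export
totalActivity <- function(track, windowDays) {
  stopifnot(is(track, "ActivityTrack"), length(windowDays) == 2)
  lo <- windowDays[1] * 86400; hi <- windowDays[2] * 86400
  if (hi <= lo) stop("window must have positive length")
  ts <- binStarts(track)
  sel <- ts >= lo & ts < hi
  if (!any(sel)) stop("window does not overlap the track")
  sum(track@distances[sel])
}
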