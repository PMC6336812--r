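#' Detrend a trace by a centered moving average
#'
#' Subtracts the centered moving average over `windowH` hours (the
#' "deviation from the moving average" convention of plate-luminometer
#' protocols); near the edges the window shrinks one-sidedly to the
#' available samples.
#'
#' @param trace a [CellTrace-class] with approximately uniform sampling and
#'   duration at least `windowH`.
#' @param windowH moving-average window in hours, default 24 (one circadian
#'   cycle, so the average tracks the baseline, not the rhythm).
#' @return a detrended [CellTrace-class].
#' @export
detrendTrace <- function(trace, windowH = 24) {
  stopifnot(is(trace, "CellTrace"))
  t <- trace@times; v <- trace@intensities
  if (diff(range(t)) < windowH)
    stop("trace must span at least one moving-average window")
  dt <- stats::median(diff(t))
  k <- max(1L, as.integer(round(windowH / 2 / dt)))
  n <- length(v)
  ma <- vapply(seq_len(n), function(i)
    mean(v[max(1, i - k):min(n, i + k)]), numeric(1))
  new("CellTrace", cellId = trace@cellId, condition = trace@condition,
      times = t, intensities = v - ma)
}

#' Normalize a trace
#'
#' `"mean"` mode divides by the time-mean of absolute values (so the
#' normalized series has mean absolute value 1); `"max_peak"` divides by
#' the maximum circadian peak intensity of the trace.
#'
#' @param trace a [CellTrace-class].
#' @param mode `"mean"` or `"max_peak"`.
#' @return a normalized [CellTrace-class].
#' @export
normalizeTrace <- function(trace, mode = c("mean", "max_peak")) {
  stopifnot(is(trace, "CellTrace"))
  mode <- match.arg(mode)
  v <- trace@intensities
  div <- switch(mode, mean = mean(abs(v)), max_peak = max(v))
  if (!is.finite(div) || div == 0)
    stop(sprintf("cannot normalize: %s of the trace is zero", mode))
  new("CellTrace", cellId = trace@cellId, condition = trace@condition,
      times = trace@times, intensities = v / div)
}

#' Fit a single-component cosinor model
#'
#' Least-squares fit of `y(t) = M + A * cos(2*pi*(t - phi)/tau)` at fixed
#' period `tau`, via the linear reparameterization
#' `y = M + beta*cos(2*pi*t/tau) + gamma*sin(2*pi*t/tau)`, so that
#' `A = sqrt(beta^2 + gamma^2)` and
#' `phi = (tau/(2*pi)) * atan2(gamma, beta) mod tau`.  Rhythmicity is
#' assessed by the zero-amplitude F-test with (2, n - 3) degrees of
#' freedom.
#'
#' @param times sample times in hours (at least 4, spanning >= one period,
#'   not all equal modulo `tau`).
#' @param values observations, same length as `times`.
#' @param period fixed period `tau` in hours, default 24, or a numeric
#'   vector of candidate periods to scan (the best-RSS period is kept).
#' @return a [CosinorFit-class].
#' @examples
#' t <- 0:47
#' fitCosinor(t, 10 + 3 * cos(2 * pi * (t - 6) / 24))
#' @export
fitCosinor <- function(times, values, period = 24) {
  stopifnot(length(times) == length(values), length(times) >= 4)
  if (diff(range(times)) < max(period))
    stop("samples must span at least one full period")
  fits <- lapply(period, function(tau) {
    w <- 2 * pi / tau
    X <- cbind(1, cos(w * times), sin(w * times))
    if (qr(X)$rank < 3)
      stop("degenerate design: sample times are aliased modulo the period")
    f <- stats::lm.fit(X, values)
    list(tau = tau, coef = f$coefficients, rss = sum(f$residuals^2))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  co <- best$coef
  A <- sqrt(co[2]^2 + co[3]^2)
  phi <- (best$tau / (2 * pi)) * atan2(co[3], co[2])
  phi <- phi %% best$tau
  if (phi >= best$tau) phi <- 0      # fp wrap of a tiny negative angle
  n <- length(values)
  rss0 <- sum((values - mean(values))^2)
  Fstat <- if (best$rss <= 0) Inf
           else ((rss0 - best$rss) / 2) / (best$rss / (n - 3))
  p <- stats::pf(Fstat, 2, n - 3, lower.tail = FALSE)
  new("CosinorFit", mesor = unname(co[1]), amplitude = unname(A),
      acrophase = unname(phi), period = best$tau,
      pValue = unname(p), rss = best$rss, n = as.integer(n))
}

#' Cosinor fit of a trace or expression course
#'
#' @param x a [CellTrace-class] or [ExpressionCourse-class].
#' @param period fixed period in hours (default 24).
#' @return a [CosinorFit-class].
#' @export
fitCosinorTrace <- function(x, period = 24) {
  fitCosinor(sampleTimes(x), intensities(x), period = period)
}

#' Extract a cell's circadian phase from its cosinor acrophase
#'
#' The phase is the acrophase mapped onto the circle:
#' `phase_rad = 2*pi*phi/tau`, in `[0, 2*pi)`.  Cells failing the
#' zero-amplitude test at `alpha` are flagged arrhythmic (phase reported
#' but to be excluded from circular summaries), never silently dropped.
#'
#' @param trace a [CellTrace-class], conventionally detrended and
#'   normalized first.
#' @param period fixed period in hours, default 24.
#' @param alpha rhythmicity threshold on the zero-amplitude p-value.
#' @return one-row data.frame: `cellId`, `condition`, `phase_rad`,
#'   `acrophase_h`, `amplitude`, `pValue`, `rhythmic`.
#' @export
extractPhase <- function(trace, period = 24, alpha = 0.05) {
  stopifnot(is(trace, "CellTrace"))
  fit <- fitCosinorTrace(trace, period = period)
  data.frame(cellId = trace@cellId, condition = trace@condition,
             phase_rad = 2 * pi * fit@acrophase / fit@period,
             acrophase_h = fit@acrophase, amplitude = fit@amplitude,
             pValue = fit@pValue, rhythmic = fit@pValue < alpha,
             stringsAsFactors = FALSE)
}

#' Circular summary of a phase sample
#'
#' Mean phase and resultant length from the complex mean
#' `sum(exp(1i*phi))/n`; circular uniformity tested with the Rayleigh
#' statistic using Zar's approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - Rn^2)) - (1 + 2n))` with `Rn = n*R`;
#' counts histogrammed over `nBins` equal angular bins starting at 0.
#'
#' @param phases numeric vector of phases in radians (n >= 2).
#' @param nBins number of angular bins, default 12 (2-h bins on a 24-h
#'   circle).
#' @return a [CircularSummary-class].
#' @examples
#' circularSummary(rep(1, 24))        # perfect synchrony, R = 1
#' @export
circularSummary <- function(phases, nBins = 12) {
  n <- length(phases)
  if (n < 2) stop("at least two phases are required")
  z <- sum(exp(1i * phases))
  R <- Mod(z) / n
  mu <- Arg(z) %% (2 * pi)
  Rn <- n * R
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  p <- min(1, max(0, p))
  breaks <- seq(0, 2 * pi, length.out = nBins + 1)
  counts <- as.integer(table(cut(phases %% (2 * pi), breaks,
                                 include.lowest = TRUE, right = FALSE)))
  new("CircularSummary", n = as.integer(n), meanPhase = mu, R = R,
      rayleighP = p, histogram = counts, breaks = breaks)
}
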