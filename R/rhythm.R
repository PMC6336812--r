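#' Re-bin an activity track to wider bins
#'
#' Sums distances within consecutive groups of source bins; total distance
#' is conserved exactly.  The target width must be an integer multiple of
#' the source width and the track length a whole number of target bins.
#'
#' @param track an [ActivityTrack-class].
#' @param newBinWidth target bin width in seconds (default 600 = 10 min).
#' @return a re-binned [ActivityTrack-class].
#' @export
rebinActivity <- function(track, newBinWidth = 600) {
  stopifnot(is(track, "ActivityTrack"))
  f <- newBinWidth / track@binWidth
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("target bin width must be an integer multiple of the source width")
  f <- as.integer(round(f))
  n <- length(track@distances)
  if (n %% f != 0)
    stop("track length must be a whole number of target bins; trim first")
  d <- colSums(matrix(track@distances, nrow = f))
  ActivityTrack(d, binWidth = newBinWidth, animalId = track@animalId,
                genotype = track@genotype, t0 = track@t0,
                schedule = track@schedule)
}

#' Build a (double-plotted) actogram matrix
#'
#' One row per 24-h day of recording.  When `doubled`, row `d` concatenates
#' day `d` and day `d+1` (48 h), padding the absent final day with zeros —
#' the standard double plot used to visualize phase drift.
#'
#' @param track an [ActivityTrack-class] whose bin width divides 86400 s
#'   (conventionally 10-min bins) and that spans at least one day.
#' @param doubled logical, default `TRUE`.
#' @return an [Actogram-class].
#' @export
buildActogram <- function(track, doubled = TRUE) {
  stopifnot(is(track, "ActivityTrack"))
  perDay <- 86400 / track@binWidth
  if (abs(perDay - round(perDay)) > 1e-9)
    stop("bin width must divide a 24-h day")
  perDay <- as.integer(round(perDay))
  x <- track@distances
  nDays <- length(x) %/% perDay
  if (nDays < 1) stop("track must span at least one full day")
  m <- matrix(x[seq_len(nDays * perDay)], nrow = nDays, byrow = TRUE)
  if (doubled) {
    nxt <- rbind(m[-1, , drop = FALSE], matrix(0, 1, perDay))
    m <- cbind(m, nxt)
  }
  new("Actogram", activity = m, doubled = doubled,
      binWidth = track@binWidth)
}

#' Chi-square (Sokolove-Bushell) periodogram
#'
#' For each candidate period P (in whole bins) the series is folded modulo
#' P into K = floor(N/P) complete cycles; with column means `M_h` over the
#' P fold positions and grand mean `Mbar` of the used bins,
#' `Qp = K * N' * sum((M_h - Mbar)^2) / sum((x_i - Mbar)^2)` where
#' `N' = K * P`.  Under the white-noise null Qp is approximately chi-square
#' with P - 1 degrees of freedom; the significance curve is the chi-square
#' quantile at `1 - alpha/m`, Bonferroni-corrected over the m scanned
#' periods.
#'
#' @param track an [ActivityTrack-class], conventionally 10-min bins,
#'   spanning at least twice the longest scanned period.
#' @param periodRange scan range in hours, default `c(16, 32)`; periods are
#'   scanned at whole-bin resolution.
#' @param alpha significance level, default 0.05.
#' @param method `"chisq"` (default) or `"lombscargle"` for the normalized
#'   Lomb-Scargle power with its exponential null, offered as an
#'   alternative statistic.
#' @return a [PeriodogramResult-class].
#' @export
chiSquarePeriodogram <- function(track, periodRange = c(16, 32),
                                 alpha = 0.05,
                                 method = c("chisq", "lombscargle")) {
  stopifnot(is(track, "ActivityTrack"))
  method <- match.arg(method)
  bw <- track@binWidth
  x <- track@distances
  N <- length(x)
  pBins <- seq(ceiling(periodRange[1] * 3600 / bw),
               floor(periodRange[2] * 3600 / bw))
  if (length(pBins) < 1) stop("period range contains no whole-bin period")
  if (N < 2 * max(pBins))
    stop("series must span at least twice the longest scanned period")
  if (stats::var(x) == 0)
    stop("zero-variance series: periodogram statistic undefined")
  m <- length(pBins)
  if (method == "lombscargle")
    return(.lombScargle(x, bw, pBins, alpha, m))
  Qp <- vapply(pBins, function(P) {
    K <- N %/% P
    xs <- x[seq_len(K * P)]
    Mh <- rowMeans(matrix(xs, nrow = P))
    Mbar <- mean(xs)
    K * length(xs) * sum((Mh - Mbar)^2) / sum((xs - Mbar)^2)
  }, numeric(1))
  thr <- stats::qchisq(1 - alpha / m, df = pBins - 1)
  peak <- which.max(Qp)
  new("PeriodogramResult", periods = pBins * bw / 3600, power = Qp,
      threshold = thr, peakPeriod = pBins[peak] * bw / 3600,
      peakPower = Qp[peak], alpha = alpha, method = "chisq")
}

# normalized Lomb-Scargle power on the same whole-bin period grid;
# null: power ~ Exp(1), Bonferroni across the m scanned periods
.lombScargle <- function(x, bw, pBins, alpha, m) {
  t <- (seq_along(x) - 1) * bw
  xc <- x - mean(x)
  s2 <- stats::var(x)
  P <- vapply(pBins, function(Pb) {
    w <- 2 * pi / (Pb * bw)
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    (sum(xc * ct)^2 / sum(ct^2) + sum(xc * st)^2 / sum(st^2)) / (2 * s2)
  }, numeric(1))
  thr <- rep(-log(1 - (1 - alpha)^(1 / m)), length(pBins))
  peak <- which.max(P)
  new("PeriodogramResult", periods = pBins * bw / 3600, power = P,
      threshold = thr, peakPeriod = pBins[peak] * bw / 3600,
      peakPower = P[peak], alpha = alpha, method = "lombscargle")
}

#' Call an animal rhythmic or arrhythmic
#'
#' Rhythmic when the periodogram peak exceeds its significance threshold
#' and the peak period lies within the circadian band (default 20-28 h;
#' significant peaks at the scan edges are treated as artifacts).
#'
#' @param result a [PeriodogramResult-class].
#' @param band circadian band in hours, default `c(20, 28)`.
#' @param animalId identifier carried into the call.
#' @return a [RhythmCall-class].
#' @export
classifyRhythmic <- function(result, band = c(20, 28), animalId = "") {
  stopifnot(is(result, "PeriodogramResult"))
  i <- which.max(result@power)
  excess <- result@peakPower - result@threshold[i]
  inBand <- result@peakPeriod >= band[1] & result@peakPeriod <= band[2]
  new("RhythmCall", animalId = as.character(animalId),
      isRhythmic = excess > 0 && inBand,
      peakPeriod = result@peakPeriod, excess = excess)
}

#' Tabulate rhythm calls
#'
#' @param calls list of [RhythmCall-class] objects.
#' @param genotype,condition optional vectors recycled along `calls`.
#' @return data.frame with one row per call.
#' @export
rhythmCallTable <- function(calls, genotype = NA, condition = NA) {
  data.frame(
    animalId = vapply(calls, function(x) x@animalId, character(1)),
    genotype = rep_len(genotype, length(calls)),
    condition = rep_len(condition, length(calls)),
    peakPeriod_h = vapply(calls, function(x) x@peakPeriod, numeric(1)),
    excess = vapply(calls, function(x) x@excess, numeric(1)),
    isRhythmic = vapply(calls, function(x) x@isRhythmic, logical(1)),
    stringsAsFactors = FALSE)
}

#' Percentage of rhythmic animals per group
#'
#' @param calls data.frame from [rhythmCallTable()] with columns
#'   `genotype`, `condition`, `isRhythmic`.
#' @return data.frame with one row per genotype x condition group:
#'   `n`, `nRhythmic`, and `percentRhythmic` rounded to whole percent.
#' @examples
#' df <- data.frame(genotype = "DKO", condition = "pulse_3h",
#'                  isRhythmic = c(rep(TRUE, 3), rep(FALSE, 8)))
#' rhythmicRatio(df)  # 27%
#' @export
rhythmicRatio <- function(calls) {
  stopifnot(all(c("genotype", "condition", "isRhythmic") %in% names(calls)))
  if (nrow(calls) == 0) stop("no rhythm calls supplied")
  key <- interaction(calls$genotype, calls$condition, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- calls[key == k, , drop = FALSE]
    data.frame(genotype = sub$genotype[1], condition = sub$condition[1],
               n = nrow(sub), nRhythmic = sum(sub$isRhythmic),
               percentRhythmic = round(100 * mean(sub$isRhythmic)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
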