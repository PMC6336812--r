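# Independent brute-force oracles used across the suite.

# element-by-element run-length encoder (no rle()): returns a data.frame of
# runs (value, start index, length)
bruteRuns <- function(states) {
  vals <- integer(0); starts <- integer(0); lens <- integer(0)
  for (i in seq_along(states)) {
    if (i == 1 || states[i] != states[i - 1]) {
      vals <- c(vals, states[i]); starts <- c(starts, i); lens <- c(lens, 1L)
    } else {
      lens[length(lens)] <- lens[length(lens)] + 1L
    }
  }
  data.frame(value = as.logical(vals), start = starts, length = lens)
}

# dense grid search over acrophase with per-phase linear regression on the
# cosine regressor; independent of the closed-form cosinor path
gridCosinor <- function(times, values, period = 24, phiStep = 0.02) {
  phis <- seq(0, period - phiStep, by = phiStep)
  best <- list(rss = Inf)
  for (phi in phis) {
    reg <- cos(2 * pi * (times - phi) / period)
    f <- lm(values ~ reg)
    rss <- sum(residuals(f)^2)
    A <- coef(f)[2]
    if (rss < best$rss && A >= 0)
      best <- list(rss = rss, M = unname(coef(f)[1]), A = unname(A),
                   phi = phi)
  }
  best
}

# direct complex-sum circular statistics plus Zar's Rayleigh formula
complexSumCircular <- function(phases) {
  n <- length(phases)
  C <- sum(cos(phases)); S <- sum(sin(phases))
  R <- sqrt(C^2 + S^2) / n
  Rn <- n * R
  list(R = R, mean = atan2(S, C) %% (2 * pi),
       p = exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n)))
}

# chi-square periodogram statistic by explicit loops on a folded series
loopQp <- function(x, P) {
  K <- length(x) %/% P
  xs <- x[1:(K * P)]
  Mh <- numeric(P)
  for (h in 1:P) {
    acc <- 0
    for (k in 0:(K - 1)) acc <- acc + xs[k * P + h]
    Mh[h] <- acc / K
  }
  Mbar <- mean(xs)
  K * length(xs) * sum((Mh - Mbar)^2) / sum((xs - Mbar)^2)
}

# rhythmicity call for a simulated track: post-pulse epoch, 10-min bins,
# default scan settings
callSimTrack <- function(tr) {
  d <- distances(tr)
  w <- pulseEnd(schedule(tr))
  d <- d[(w + 1):length(d)]
  keep <- (length(d) %/% 600L) * 600L
  t10 <- rebinActivity(ActivityTrack(d[seq_len(keep)], 1), 600)
  classifyRhythmic(chiSquarePeriodogram(t10))
}

restStatsSimTrack <- function(tr, threshold = 60) {
  w <- pulseEnd(schedule(tr))
  computeRestStats(trackBouts(tr), threshold,
                   window = c(w, trackDuration(tr)))
}
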