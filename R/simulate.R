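.setSeed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

# time-averaged resting fraction of the alternating-renewal model when the
# rest-initiation rate is modulated by 1 + d*cos(theta): each time of day
# occupies equal time and the process is locally stationary (active periods
# are much shorter than 24 h), so the daily fraction is the uniform average
# over theta of mr / (mr + ma/(1 + d*cos(theta)))
.restFraction <- function(mr, ma, d) {
  theta <- seq(0, 2 * pi, length.out = 721)[-721]
  mean(mr / (mr + ma / pmax(1 + d * cos(theta), 0.05)))
}

#' Genotype presets for the behavioral simulator
#'
#' Returns the calibrated [GenotypePreset-class] for a genotype.  The mean
#' rest-bout duration is solved numerically so the expected resting time
#' per day under a 12-h light pulse equals the genotype's target (7.8 h
#' WT, 20.5 h DKO, 20.6 h TKO — the sleep-architecture contrast the bout
#' analysis quantifies), accounting for the circadian modulation of rest
#' initiation.  Modulation depths encode the light-history ordering of
#' rhythm formation: WT entrains strongly after either pulse, the double
#' knockout only after a 12-h pulse, and the triple knockout not at all.
#'
#' @param name `"WT"`, `"DKO"` or `"TKO"`.
#' @return a [GenotypePreset-class].
#' @examples
#' genotypePreset("WT")
#' @export
genotypePreset <- function(name = c("WT", "DKO", "TKO")) {
  name <- match.arg(name)
  p <- switch(name,
    WT = list(target_h = 7.8, ma_h = 0.25,
              mod = c(DD = 0, pulse_3h = 0.9, pulse_12h = 0.9),
              pauseRate = 2, pause_s = 5, dist = 0.10),
    DKO = list(target_h = 20.5, ma_h = 0.1,
               mod = c(DD = 0, pulse_3h = 0.05, pulse_12h = 0.8),
               pauseRate = 3, pause_s = 8, dist = 0.05),
    TKO = list(target_h = 20.6, ma_h = 0.1,
               mod = c(DD = 0, pulse_3h = 0.05, pulse_12h = 0.05),
               pauseRate = 3, pause_s = 8, dist = 0.05))
  maS <- p$ma_h * 3600
  target <- p$target_h / 24
  mr <- stats::uniroot(function(m)
    .restFraction(m, maS, p$mod[["pulse_12h"]]) - target,
    interval = c(1, 1e6), tol = 1e-6)$root
  new("GenotypePreset", name = name, meanRestBout = mr,
      meanActivePeriod = p$ma_h, sdlog = 0.6,
      shortPauseRate = p$pauseRate, meanShortPause = p$pause_s,
      distMean = p$dist, distShape = 0.3, modDepth = p$mod, phi0 = 18)
}

#' Simulate one larval locomotor track
#'
#' Alternating-renewal model at 1-s resolution: lognormal active periods
#' alternate with lognormal rest bouts; within active periods, movement
#' runs (gamma-distributed per-second distances) are interrupted by short
#' (< 60 s) exponential pauses at the preset rate.  After the light pulse
#' the rest-initiation rate is modulated by
#' `1 + d * cos(2*pi*(t - phi0)/24 h)` with depth `d` from the preset for
#' the schedule's condition; before or without light history there is no
#' modulation, emulating the dispersed cellular clock phases of dark-reared
#' animals.
#'
#' @param preset a [GenotypePreset-class].
#' @param durationDays days of constant-dark recording after the light
#'   pulse (default 4); the track additionally covers the pulse itself, so
#'   it starts at light onset (`t0 = 0`).
#' @param schedule a [LightSchedule-class] (default 12-h pulse).
#' @param animalId identifier for the track.
#' @param seed optional seed (`NULL` uses the current RNG state).
#' @return an [ActivityTrack-class] with 1-s bins.
#' @export
simulateTrack <- function(preset, durationDays = 4,
                          schedule = LightSchedule("pulse_12h"),
                          animalId = "sim", seed = NULL) {
  stopifnot(is(preset, "GenotypePreset"))
  .setSeed(seed)
  pulseOff <- pulseEnd(schedule)
  total <- as.integer(pulseOff + durationDays * 86400)
  depth <- if (schedule@label %in% names(preset@modDepth))
    preset@modDepth[[schedule@label]] else 0
  maS <- preset@meanActivePeriod * 3600
  mrS <- preset@meanRestBout
  sdl <- preset@sdlog
  interPause <- 60 / preset@shortPauseRate

  runLen <- vector("list", 4096L); runVal <- vector("list", 4096L)
  nr <- 0L
  add <- function(len, val) {
    nr <<- nr + 1L
    runLen[[nr]] <<- len; runVal[[nr]] <<- val
  }
  t <- 0
  repeat {
    d_t <- if (t >= pulseOff) depth else 0
    gate <- pmax(1 + d_t * cos(2 * pi * (t / 3600 - preset@phi0) / 24), 0.05)
    Da <- max(1, round(stats::rlnorm(1, log(maS / gate) - sdl^2 / 2, sdl)))
    Da <- min(Da, total - t)
    rem <- Da
    len <- numeric(0); val <- logical(0)
    while (rem > 0) {
      mv <- min(max(1, round(stats::rexp(1, 1 / interPause))), rem)
      len <- c(len, mv); val <- c(val, TRUE); rem <- rem - mv
      if (rem > 0) {
        pa <- min(max(1, round(stats::rexp(1, 1 / preset@meanShortPause))),
                  59, rem)
        len <- c(len, pa); val <- c(val, FALSE); rem <- rem - pa
      }
    }
    add(len, val)
    t <- t + Da
    if (t >= total) break
    Dr <- max(1, round(stats::rlnorm(1, log(mrS) - sdl^2 / 2, sdl)))
    Dr <- min(Dr, total - t)
    add(Dr, FALSE)
    t <- t + Dr
    if (t >= total) break
  }
  moving <- inverse.rle(list(
    lengths = unlist(runLen[seq_len(nr)]),
    values = unlist(runVal[seq_len(nr)])))
  dist <- numeric(total)
  nmv <- sum(moving)
  dist[moving] <- stats::rgamma(nmv, shape = preset@distShape,
                                scale = preset@distMean / preset@distShape)
  ActivityTrack(dist, binWidth = 1, animalId = animalId,
                genotype = if (preset@name %in% GENOTYPES) preset@name
                           else "custom",
                t0 = 0, schedule = schedule)
}

#' Simulate a cohort of tracks
#'
#' @param preset a [GenotypePreset-class].
#' @param n number of animals.
#' @param durationDays post-pulse days per track.
#' @param schedule a [LightSchedule-class].
#' @param seed optional seed for the whole cohort.
#' @param idPrefix prefix for animal ids.
#' @return named list of [ActivityTrack-class] objects.
#' @export
simulateCohort <- function(preset, n = 12, durationDays = 4,
                           schedule = LightSchedule("pulse_12h"),
                           seed = NULL, idPrefix = NULL) {
  .setSeed(seed)
  if (is.null(idPrefix))
    idPrefix <- paste0(preset@name, "_", schedule@label)
  tracks <- lapply(seq_len(n), function(i)
    simulateTrack(preset, durationDays, schedule,
                  animalId = sprintf("%s_%02d", idPrefix, i)))
  names(tracks) <- vapply(tracks, animalId, character(1))
  tracks
}

#' Construct oscillator parameters
#'
#' @param period period in hours (default 24).
#' @param amplitude oscillation amplitude (default 2).
#' @param damping fractional amplitude loss per day (default 0.05;
#'   cultured-cell reporter rhythms damp slowly).
#' @param noiseSd additive Gaussian noise sd (default 0.1).
#' @param trendSlope fractional baseline drift per hour (default 0).
#' @param phaseMode `"uniform_random"` (dark condition: cell-autonomous
#'   clocks free-run out of phase) or `"common"` (light-synchronized).
#' @param commonPhaseSd phase spread in hours in common mode (default 1).
#' @param phi0 common acrophase in hours after light onset (default 6).
#' @param baseline baseline intensity (default 10).
#' @return an [OscillatorParams-class].
#' @export
OscillatorParams <- function(period = 24, amplitude = 2, damping = 0.05,
                             noiseSd = 0.1, trendSlope = 0,
                             phaseMode = c("uniform_random", "common"),
                             commonPhaseSd = 1, phi0 = 6, baseline = 10) {
  phaseMode <- match.arg(phaseMode)
  new("OscillatorParams", period = period, amplitude = amplitude,
      damping = damping, noiseSd = noiseSd, trendSlope = trendSlope,
      phaseMode = phaseMode, commonPhaseSd = commonPhaseSd, phi0 = phi0,
      baseline = baseline)
}

#' Simulate single-cell bioluminescence traces
#'
#' `intensity(t) = baseline*(1 + trendSlope*t) +
#'  amplitude*(1 - damping)^(t/24)*cos(2*pi*(t - phi_cell)/period) + noise`,
#' with per-cell acrophase `phi_cell` uniform on `[0, period)` in
#' `uniform_random` mode, or wrapped-normal around `phi0` in `common` mode.
#'
#' @param params an [OscillatorParams-class].
#' @param n number of cells (default 24).
#' @param durationH recording length in hours (default 72).
#' @param dtH sampling interval in hours (default 0.5).
#' @param condition condition label; defaults to `"dark"` for uniform
#'   phases and `"light_12h"` for common phases.
#' @param seed optional seed.
#' @return list of [CellTrace-class]; the true per-cell acrophases are
#'   attached as `attr(, "truePhase_h")`.
#' @export
simulateCells <- function(params, n = 24, durationH = 72, dtH = 0.5,
                          condition = NULL, seed = NULL) {
  stopifnot(is(params, "OscillatorParams"))
  .setSeed(seed)
  if (is.null(condition))
    condition <- if (params@phaseMode == "common") "light_12h" else "dark"
  t <- seq(0, durationH, by = dtH)
  phis <- numeric(n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    phi <- if (params@phaseMode == "uniform_random")
      stats::runif(1, 0, params@period)
    else (stats::rnorm(1, params@phi0, params@commonPhaseSd)) %% params@period
    phis[i] <- phi
    v <- params@baseline * (1 + params@trendSlope * t) +
      params@amplitude * (1 - params@damping)^(t / 24) *
        cos(2 * pi * (t - phi) / params@period)
    if (params@noiseSd > 0) v <- v + stats::rnorm(length(t), 0, params@noiseSd)
    traces[[i]] <- CellTrace(t, v, cellId = sprintf("cell_%02d", i),
                             condition = condition)
  }
  names(traces) <- vapply(traces, function(x) x@cellId, character(1))
  attr(traces, "truePhase_h") <- phis
  traces
}

#' Simulate a light-inducible or clock-output expression course
#'
#' Four canonical shapes of relative expression after light onset:
#' * `"acute_inducible"`: pulse peaking at 3 h then decaying (the fast
#'   light-induced clock genes);
#' * `"slow_inducible"`: slower rise peaking near 12 h (the slowly
#'   light-induced genes);
#' * `"clock_output"`: `1 + a*cos(2*pi*(t - phi)/24)` when `synchronized`
#'   (clock-target genes oscillating after an entraining pulse), flat
#'   otherwise;
#' * `"flat"`: constant 1.
#' Multiplicative lognormal noise is applied, then the course is
#' renormalized so the value at time 0 is 1.
#'
#' @param kind one of the four shapes.
#' @param times sample times in hours after light onset, including 0
#'   (default every 3 h to 24 h).
#' @param foldInduction peak fold-change of the inducible shapes
#'   (default 10).
#' @param a relative amplitude of the clock-output cosine (default 0.5).
#' @param phi clock-output acrophase in hours (default 12).
#' @param synchronized does the clock output actually oscillate
#'   (genotype-by-light condition)?  Default `TRUE`.
#' @param noiseSdLog lognormal noise sd on the log scale (default 0.1).
#' @param gene gene name.
#' @param seed optional seed.
#' @return an [ExpressionCourse-class].
#' @export
simulateExpression <- function(kind = c("acute_inducible", "slow_inducible",
                                        "clock_output", "flat"),
                               times = seq(0, 24, by = 3),
                               foldInduction = 10, a = 0.5, phi = 12,
                               synchronized = TRUE, noiseSdLog = 0.1,
                               gene = NULL, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(0 %in% times)
  .setSeed(seed)
  pulseShape <- function(tp) (times / tp)^2 * exp(2 * (1 - times / tp))
  v <- switch(kind,
    acute_inducible = 1 + (foldInduction - 1) * pulseShape(3),
    slow_inducible = 1 + (foldInduction - 1) * pulseShape(12),
    clock_output = if (synchronized) 1 + a * cos(2 * pi * (times - phi) / 24)
                   else rep(1, length(times)),
    flat = rep(1, length(times)))
  if (noiseSdLog > 0)
    v <- v * exp(stats::rnorm(length(v), 0, noiseSdLog))
  ExpressionCourse(times, v, gene = if (is.null(gene)) kind else gene)
}

#' Simulate a pooled immobile-bout length sample with a survival crossover
#'
#' Generates immobile-bout lengths whose log-log survival curve changes
#' regime at `crossover` seconds — the changepoint that
#' [estimateRestThreshold()] recovers.
#'
#' The default `"piecewise_pareto"` family draws from a two-regime
#' power-law survival, `S(x) = (x/xmin)^(-aShort)` up to the crossover and
#' `S(c) * (x/c)^(-aLong)` beyond it (behavioral bout lengths are heavy
#' tailed, and a two-regime power law is the construction whose log-log
#' survival actually *is* a broken line with its kink at the crossover).
#' The `"exp_lognormal"` family is a mixture of exponential short pauses
#' and lognormal long rests whose component survivals cross at the target
#' (`w * exp(-c/pauseMean) = (1 - w) * S_LN(c)`); its log-log survival
#' bends smoothly rather than kinking, so the changepoint estimate from it
#' is much less precise — it is provided for realism comparisons.
#'
#' @param n number of bouts (default 5000).
#' @param crossover target changepoint in seconds (default 60).
#' @param family `"piecewise_pareto"` (default) or `"exp_lognormal"`.
#' @param aShort,aLong log-log survival slopes before/after the crossover
#'   (defaults 0.5 and 2).
#' @param xmin shortest possible bout in seconds (default 1).
#' @param pauseMean exponential pause mean in seconds (default 15),
#'   `exp_lognormal` only.
#' @param restMedian,restSdlog lognormal rest parameters (defaults 300 s,
#'   sdlog 1), `exp_lognormal` only.
#' @param seed optional seed.
#' @return integer vector of bout lengths (seconds, >= `xmin`).
#' @export
simulateRestBoutMixture <- function(n = 5000, crossover = 60,
                                    family = c("piecewise_pareto",
                                               "exp_lognormal"),
                                    aShort = 0.5, aLong = 2, xmin = 1,
                                    pauseMean = 15, restMedian = 300,
                                    restSdlog = 1, seed = NULL) {
  family <- match.arg(family)
  .setSeed(seed)
  if (family == "piecewise_pareto") {
    sC <- (crossover / xmin)^(-aShort)   # survival at the crossover
    u <- stats::runif(n)                 # u is the survival quantile
    x <- ifelse(u > sC,
                xmin * u^(-1 / aShort),
                crossover * (u / sC)^(-1 / aLong))
  } else {
    sExp <- exp(-crossover / pauseMean)
    sLn <- stats::plnorm(crossover, log(restMedian), restSdlog,
                         lower.tail = FALSE)
    w <- sLn / (sLn + sExp)
    isPause <- stats::runif(n) < w
    x <- numeric(n)
    x[isPause] <- stats::rexp(sum(isPause), 1 / pauseMean)
    x[!isPause] <- stats::rlnorm(sum(!isPause), log(restMedian), restSdlog)
  }
  pmax(as.integer(xmin), as.integer(round(x)))
}
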