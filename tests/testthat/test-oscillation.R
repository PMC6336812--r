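test_that("moving-average detrending removes trends and constants", {
  t <- seq(0, 72, by = 0.5)
  ramp <- CellTrace(t, 5 + 0.3 * t)
  dt <- detrendTrace(ramp)
  interior <- t >= 12 & t <= 60
  expect_lt(max(abs(intensities(dt)[interior])), 1e-9 * 0.3 * 24)

  const <- detrendTrace(CellTrace(t, rep(7, length(t))))
  expect_equal(intensities(const), rep(0, length(t)))

  # cosine survives detrending of an added linear trend
  pure <- cos(2 * pi * (t - 8) / 24)
  dt2 <- detrendTrace(CellTrace(t, 100 + 0.5 * t + pure))
  expect_gt(cor(intensities(dt2)[interior], pure[interior]), 0.99)

  expect_error(detrendTrace(CellTrace(0:10, rnorm(11))), "window")
})

test_that("normalization modes scale as documented", {
  t <- 0:30
  tr <- CellTrace(t, rep(5, 31))
  expect_equal(intensities(normalizeTrace(tr, "mean")), rep(1, 31))

  set.seed(61)
  v <- rnorm(31, 10, 2)
  n1 <- normalizeTrace(CellTrace(t, v), "mean")
  n10 <- normalizeTrace(CellTrace(t, 10 * v), "mean")
  expect_equal(intensities(n1), intensities(n10))   # scale invariance
  expect_equal(mean(abs(intensities(n1))), 1)

  npk <- normalizeTrace(CellTrace(t, v), "max_peak")
  expect_equal(max(intensities(npk)), 1)
  expect_error(normalizeTrace(CellTrace(t, rep(0, 31)), "mean"), "zero")
})

test_that("cosinor recovers a noiseless cosine exactly", {
  t <- 0:47
  f <- fitCosinor(t, 10 + 3 * cos(2 * pi * (t - 6) / 24))
  expect_equal(mesor(f), 10, tolerance = 1e-9)
  expect_equal(amplitude(f), 3, tolerance = 1e-9)
  expect_equal(acrophase(f), 6, tolerance = 1e-9)
  expect_lt(f@pValue, 1e-12)

  fconst <- fitCosinor(t, rep(4, 48))
  expect_lt(amplitude(fconst), 1e-9)
  expect_gt(fconst@pValue, 0.99)

  expect_error(fitCosinor(c(0, 24, 48, 72), c(1, 2, 1, 2)), "aliased")
  expect_error(fitCosinor(0:10, rnorm(11)), "span")
})

test_that("noisy cosinor fits agree with a dense grid-search oracle", {
  set.seed(62)
  t <- 0:47
  okA <- 0; okPhi <- 0
  for (i in 1:12) {
    y <- 10 + 3 * cos(2 * pi * (t - 6) / 24) + rnorm(48, 0, 0.5)
    f <- fitCosinor(t, y)
    g <- gridCosinor(t, y)
    expect_equal(amplitude(f), g$A, tolerance = 0.01)
    dphi <- abs(((acrophase(f) - g$phi + 12) %% 24) - 12)
    expect_lt(dphi, 0.03)
    okA <- okA + (abs(amplitude(f) - 3) / 3 < 0.1)
    okPhi <- okPhi + (abs(((acrophase(f) - 6 + 12) %% 24) - 12) < 0.5)
  }
  expect_gte(okA, 11); expect_gte(okPhi, 11)
})

test_that("free-period scan locks onto the true period", {
  t <- seq(0, 72, by = 1)
  y <- 2 + cos(2 * pi * (t - 3) / 26)
  f <- fitCosinor(t, y, period = seq(20, 30, by = 0.5))
  expect_equal(f@period, 26)
})

test_that("phase extraction maps acrophase onto the circle", {
  t <- seq(0, 72, by = 0.5)
  ph6 <- extractPhase(CellTrace(t, cos(2 * pi * (t - 6) / 24)))
  expect_equal(ph6$phase_rad, pi / 2, tolerance = 1e-9)
  expect_true(ph6$rhythmic)
  ph0 <- extractPhase(CellTrace(t, cos(2 * pi * t / 24)))
  # phase 0 and 2*pi are the same point on the circle
  expect_lt(min(ph0$phase_rad, 2 * pi - ph0$phase_rad), 1e-9)
  # arrhythmic cells are flagged, not dropped; a 12-h harmonic is
  # orthogonal to the 24-h regressors, hence deterministically arrhythmic
  flat <- extractPhase(CellTrace(t, 10 + cos(2 * pi * t / 12)))
  expect_false(flat$rhythmic)
  expect_equal(nrow(flat), 1)
})

test_that("circular summaries match the complex-sum oracle and its symmetries", {
  s <- circularSummary(rep(1.3, 24))
  expect_equal(resultantLength(s), 1)
  expect_lt(rayleighP(s), 1e-6)
  expect_equal(sum(s@histogram), 24L)

  even <- seq(0, 2 * pi, length.out = 25)[-25]
  expect_lt(resultantLength(circularSummary(even)), 1e-12)

  set.seed(64)
  for (i in 1:10) {
    ph <- runif(sample(5:40, 1), 0, 2 * pi)
    s <- circularSummary(ph)
    o <- complexSumCircular(ph)
    expect_equal(resultantLength(s), o$R)
    expect_equal(meanPhase(s), o$mean)
    expect_equal(rayleighP(s), min(1, o$p))
    # rotation equivariance
    rot <- circularSummary((ph + 1.1) %% (2 * pi))
    expect_equal(resultantLength(rot), o$R, tolerance = 1e-12)
    expect_equal(meanPhase(rot), (o$mean + 1.1) %% (2 * pi),
                 tolerance = 1e-9)
  }
  expect_error(circularSummary(1), "two phases")
})

test_that("uniform phase samples rarely reject uniformity", {
  set.seed(65)
  ps <- replicate(40, rayleighP(circularSummary(runif(24, 0, 2 * pi))))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("detrend-normalize-fit recovers the phase of a damped oscillator", {
  set.seed(66)
  params <- OscillatorParams(damping = 0.1, noiseSd = 0.1,
                             trendSlope = -0.003,
                             phaseMode = "uniform_random")
  cells <- simulateCells(params, n = 12)
  truth <- attr(cells, "truePhase_h")
  est <- vapply(cells, function(tr) {
    extractPhase(normalizeTrace(detrendTrace(tr), "mean"))$acrophase_h
  }, numeric(1))
  err <- abs(((est - truth + 12) %% 24) - 12)
  expect_lt(max(err), 0.5)
})

test_that("cosinor rhythm calls on expression courses have power and size", {
  set.seed(67)
  rej <- function(kind, n) mean(replicate(n, {
    e <- simulateExpression(kind, times = seq(0, 24, by = 3))
    fitCosinorTrace(e)@pValue < 0.05
  }))
  expect_gte(rej("clock_output", 60), 0.9)
  expect_lte(rej("flat", 60), 0.08)
})
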