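test_that("bin classification thresholds distances against epsilon", {
  expect_equal(classifyBins(ActivityTrack(rep(0, 10))), rep(FALSE, 10))
  expect_equal(classifyBins(ActivityTrack(c(0, 0.2, 0))),
               c(FALSE, TRUE, FALSE))
  expect_error(classifyBins(ActivityTrack(1:5, binWidth = 600)), "1-s bins")

  set.seed(21)
  d <- runif(10000, 0, 0.2)
  expect_identical(classifyBins(ActivityTrack(d), epsilon = 0.05), d > 0.05)
})

test_that("bout segmentation matches a brute-force run-length encoder", {
  # fixed patterns
  bt <- segmentBouts(rep(FALSE, 600))
  expect_equal(boutData(bt)$state, "immobile")
  expect_equal(boutData(bt)$duration_s, 600)

  states <- c(rep(TRUE, 30), rep(FALSE, 90), rep(TRUE, 10))
  b <- boutData(segmentBouts(states, distances = rep(1, 130)))
  expect_equal(b$state, c("active", "immobile", "active"))
  expect_equal(b$duration_s, c(30, 90, 10))
  expect_equal(b$distance_mm, c(30, 0, 10))

  # random property: equality with the element-wise oracle
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:300, 1)
    states <- runif(n) < runif(1)
    d <- runif(n)
    b <- boutData(segmentBouts(states, d))
    o <- bruteRuns(states)
    expect_equal(nrow(b), nrow(o))
    expect_equal(b$state == "active", o$value)
    expect_equal(b$duration_s, o$length)
    expect_equal(b$start_s, o$start - 1)
    dist <- mapply(function(s, l) sum(d[s:(s + l - 1)]), o$start, o$length)
    dist[!o$value] <- 0
    expect_equal(b$distance_mm, dist)
  }
})

test_that("bout durations partition the track with alternating states", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(50:2000, 1)
    tr <- ActivityTrack(rbinom(n, 1, 0.4) * runif(n))
    b <- boutData(trackBouts(tr))
    expect_equal(sum(b$duration_s), trackDuration(tr))
    expect_equal(b$start_s, cumsum(c(0, head(b$duration_s, -1))))
    if (nrow(b) > 1)
      expect_true(all(b$state[-1] != b$state[-nrow(b)]))
  }
})

test_that("bout-length ecdf equals a sort-and-count oracle", {
  e <- boutEcdf(c(10, 10, 20))
  expect_equal(e@lengths, c(10, 20))
  expect_equal(e@cumProb, c(2 / 3, 1))

  e1 <- boutEcdf(42)
  expect_equal(e1@cumProb, 1)

  set.seed(33)
  x <- pmax(1, round(rlnorm(5000, 3, 1)))
  e <- boutEcdf(x)
  u <- sort(unique(x))
  cp <- vapply(u, function(v) sum(x <= v) / length(x), numeric(1))
  expect_equal(e@lengths, u)
  expect_equal(e@cumProb, cp)
  expect_error(boutEcdf(numeric(0)), "at least one")
})

test_that("rest statistics reproduce the hand-derived worked example", {
  # 600-s track: A 100 s (50 mm), I 30 s, A 70 s (21 mm), I 120 s,
  # A 280 s (84 mm); threshold 60 s
  d <- c(rep(0.5, 100), rep(0, 30), rep(0.3, 70), rep(0, 120),
         rep(0.3, 280))
  st <- computeRestStats(trackBouts(ActivityTrack(d)), restThreshold = 60)
  expect_equal(st$restingTime_h_per_day, 120 / 600 * 24)
  expect_equal(st$nActiveRestCycles, 1)
  expect_equal(st$meanActivePeriod_h, 240 / 3600)
  expect_equal(st$meanDistancePerActivePeriod_mm, 77.5)
})

test_that("an entirely immobile day is 24 h of rest with no active period", {
  st <- computeRestStats(trackBouts(ActivityTrack(rep(0, 86400))))
  expect_equal(st$restingTime_h_per_day, 24)
  expect_equal(st$nActiveRestCycles, 1)
  expect_true(is.na(st$meanActivePeriod_h))
  expect_true(is.na(st$meanDistancePerActivePeriod_mm))
})

test_that("rest + active-period time partitions the window; resting time is monotone in the threshold", {
  set.seed(34)
  for (i in 1:10) {
    n <- 20000
    tr <- ActivityTrack(rbinom(n, 1, 0.55) * runif(n))
    bt <- trackBouts(tr)
    thetas <- c(5, 20, 60, 180, 600)
    rests <- vapply(thetas, function(th)
      computeRestStats(bt, th)$restingTime_h_per_day, numeric(1))
    expect_true(all(diff(rests) <= 1e-9))
  }
  # partition identity on tracks bounded by rest bouts: every active
  # period is complete, and rest time + mean period length x period count
  # recovers the window exactly (periods = rest bouts - 1)
  for (i in 1:10) {
    n <- 20000
    d <- rbinom(n, 1, 0.55) * runif(n)
    d[c(1:120, (n - 119):n)] <- 0
    st <- computeRestStats(trackBouts(ActivityTrack(d)), 60)
    nPeriods <- st$nActiveRestCycles - 1
    expect_equal(st$restingTime_h_per_day / 24 * n +
                   st$meanActivePeriod_h * 3600 * nPeriods, n)
  }
})

test_that("windowing clips censored bouts out of the per-period means", {
  # rest [0,100) | active [100,150) (25 mm) | rest [150,230) |
  # active [230,300) (35 mm) | rest [300,390)
  d <- c(rep(0, 100), rep(0.5, 50), rep(0, 80), rep(0.5, 70), rep(0, 90))
  bt <- trackBouts(ActivityTrack(d))
  # window [120, 340): the first active period starts before the window
  st <- computeRestStats(bt, 60, window = c(120, 340))
  # in-window rest: [150,230) whole (80 s) + [300,390) clipped to 40 s
  expect_equal(st$restingTime_h_per_day, (80 + 40) / 220 * 24)
  # only [150,230) lies fully inside
  expect_equal(st$nActiveRestCycles, 1)
  # active periods: [100,150) censored by the window edge -> excluded from
  # the means; [230,300) complete
  expect_equal(st$meanActivePeriod_h, 70 / 3600)
  expect_equal(st$meanDistancePerActivePeriod_mm, 35)
  expect_error(computeRestStats(bt, 60, window = c(120, 150)), "at least")
})

test_that("total activity sums windows and is invariant to re-binning", {
  expect_equal(totalActivity(ActivityTrack(rep(0, 1200)), c(0, 1)), 0)
  two_days <- ActivityTrack(rep(1, 2 * 86400))
  expect_equal(totalActivity(two_days, c(0, 2)), 172800)
  set.seed(35)
  tr <- ActivityTrack(runif(2 * 86400))
  t10 <- rebinActivity(tr, 600)
  expect_equal(totalActivity(tr, c(0.25, 1.75)),
               totalActivity(t10, c(0.25, 1.75)))
  expect_error(totalActivity(tr, c(1, 1)), "positive length")
  expect_error(totalActivity(tr, c(5, 6)), "overlap")
})
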