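test_that("domain-type validity rejects malformed objects", {
  expect_error(ActivityTrack(c(1, -0.5)), "non-negative")
  expect_error(ActivityTrack(c(1, NA)), "finite")
  expect_error(ActivityTrack(1, binWidth = 0), "positive")
  expect_error(ActivityTrack(1, genotype = "mutantX"), "genotype")
  expect_error(CellTrace(c(1, 1, 2), c(0, 0, 0)), "strictly increasing")
  expect_error(CellTrace(1:3, c(1, Inf, 2)), "finite")
  expect_error(ExpressionCourse(c(0, 3), c(1, -2), normalize = FALSE),
               "positive")
  expect_error(LightSchedule("custom", matrix(c(0, 3600, 1800, 7200),
                                              ncol = 2, byrow = TRUE)),
               "non-overlapping")
  expect_error(AnalysisConfig(alpha = 1.2), "alpha")
})

test_that("light-schedule presets carry the expected pulse history", {
  expect_equal(pulseEnd(LightSchedule("DD")), 0)
  expect_equal(pulseEnd(LightSchedule("pulse_3h")), 3 * 3600)
  expect_equal(pulseEnd(LightSchedule("pulse_12h")), 12 * 3600)
})

test_that("expression courses normalize the first timepoint to 1", {
  ec <- ExpressionCourse(c(0, 3, 6), c(4, 12, 8))
  expect_equal(intensities(ec), c(1, 3, 2))
})

test_that("activity tables round-trip through CSV", {
  tracks <- list(
    ActivityTrack(c(0, 0.3, 0.1, 0, 0.2), animalId = "f1", genotype = "WT"),
    ActivityTrack(c(0.5, 0, 0, 0.8, 0), animalId = "f2", genotype = "DKO"))
  names(tracks) <- c("f1", "f2")
  path <- withr::local_tempfile(fileext = ".csv")
  writeTracks(tracks, path)
  back <- readActivityTable(path)
  expect_length(back, 2)
  for (id in names(tracks)) {
    expect_equal(distances(back[[id]]), distances(tracks[[id]]))
    expect_equal(genotype(back[[id]]), genotype(tracks[[id]]))
    expect_equal(binWidth(back[[id]]), binWidth(tracks[[id]]))
  }
})

test_that("activity reader rejects bad files with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(animal_id = "a", genotype = "WT", time_s = 0:1,
                       distance_mm = c(1, -2)), path, row.names = FALSE)
  expect_error(readActivityTable(path), "negative distance")

  write.csv(data.frame(animal_id = "a", genotype = "WT", time_s = 0:1,
                       distance_mm = c("1", "oops")), path, row.names = FALSE)
  expect_error(readActivityTable(path), "non-numeric")

  write.csv(data.frame(animal_id = "a", time_s = 0:1, distance_mm = 0:1),
            path, row.names = FALSE)
  expect_error(readActivityTable(path), "genotype")
})

test_that("missing bins are an error unless zero-fill is requested", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(animal_id = "a", genotype = "WT",
                       time_s = c(0, 1, 3), distance_mm = c(1, 2, 3)),
            path, row.names = FALSE)
  expect_error(readActivityTable(path), "missing bins")
  back <- readActivityTable(path, schema = tableSchema(fillGaps = TRUE))
  expect_equal(distances(back[["a"]]), c(1, 2, 0, 3))
})

test_that("trace tables round-trip, sort times, and reject duplicates", {
  set.seed(11)
  traces <- lapply(1:3, function(i)
    CellTrace(seq(0, 49.5, by = 0.5), rnorm(100, 10),
              cellId = paste0("c", i),
              condition = if (i == 1) "dark" else "light_12h"))
  names(traces) <- paste0("c", 1:3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTraces(traces, path)
  back <- readTraceTable(path)
  expect_length(back, 3)
  expect_equal(intensities(back[["c2"]]), intensities(traces[["c2"]]))
  expect_equal(condition(back[["c1"]]), "dark")

  # unsorted rows come back sorted
  df <- data.frame(cell_id = "c", condition = "dark",
                   time_h = c(2, 0, 1), intensity = c(30, 10, 20))
  write.csv(df, path, row.names = FALSE)
  tr <- readTraceTable(path)[["c"]]
  expect_equal(sampleTimes(tr), c(0, 1, 2))
  expect_equal(intensities(tr), c(10, 20, 30))

  df$time_h <- c(0, 0, 1)
  write.csv(df, path, row.names = FALSE)
  expect_error(readTraceTable(path), "duplicate")
  write.csv(df[0, ], path, row.names = FALSE)
  expect_error(readTraceTable(path), "no data rows")
})

test_that("expression tables round-trip", {
  courses <- list(a = ExpressionCourse(c(0, 3, 6, 12), c(2, 20, 10, 4),
                                       gene = "a"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeExpressionTable(courses, path)
  back <- readExpressionTable(path)
  expect_equal(intensities(back[["a"]]), intensities(courses[["a"]]))
})

test_that("writeResults emits one CSV per table plus metadata, deterministically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  tabs <- list(stats = data.frame(animalId = paste0("f", 1:5), x = 1:5))
  m1 <- writeResults(tabs, dir1, config = AnalysisConfig(), seed = 3L)
  expect_setequal(m1$file, c("stats.csv", "run_metadata.json"))
  expect_equal(nrow(read.csv(file.path(dir1, "stats.csv"))), 5)
  writeResults(tabs, dir2, config = AnalysisConfig(), seed = 3L)
  expect_identical(readBin(file.path(dir1, "stats.csv"), "raw", 1e5),
                   readBin(file.path(dir2, "stats.csv"), "raw", 1e5))

  m0 <- writeResults(list(), withr::local_tempdir())
  expect_equal(m0$file, "run_metadata.json")
})

test_that("analysis configs round-trip through JSON", {
  cfg <- AnalysisConfig(movementEpsilon = 0.01, restThreshold = 45,
                        periodRange = c(18, 30), alpha = 0.01,
                        activityWindow = c(43200, 388800), seed = 9L)
  path <- withr::local_tempfile(fileext = ".json")
  writeConfig(cfg, path)
  back <- readConfig(path)
  expect_equal(configAsList(back), configAsList(cfg))
})
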