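.trackWindow <- function(track, config) {
  if (!all(is.na(config@activityWindow))) return(config@activityWindow)
  start <- max(pulseEnd(schedule(track)), track@t0)
  c(start, track@t0 + trackDuration(track))
}

#' Run the full behavioral pipeline on a cohort of tracks
#'
#' For each 1-s track: classify bins, segment bouts, compute the
#' rest/activity statistics over the analysis window (by default the
#' post-pulse constant-dark epoch), re-bin to 10 minutes, compute the
#' chi-square periodogram over the post-pulse epoch, and call rhythmicity.
#' Animals failing any stage are quarantined with a logged reason rather
#' than aborting the cohort; the run errors only if no animal succeeds.
#'
#' @param tracks list of [ActivityTrack-class] objects with 1-s bins.
#' @param config an [AnalysisConfig-class].
#' @return list with elements `stats` (per-animal rest/activity table),
#'   `calls` (per-animal rhythm-call table), `ratios` (per genotype x
#'   condition percentage table), `failures` (animal, reason), and
#'   `manifest` (config echo, seed, counts).
#' @export
runBehaviorPipeline <- function(tracks, config = AnalysisConfig()) {
  stopifnot(length(tracks) >= 1)
  statsRows <- list(); callRows <- list(); fails <- list()
  for (tr in tracks) {
    res <- tryCatch({
      window <- .trackWindow(tr, config)
      bt <- trackBouts(tr, epsilon = config@movementEpsilon)
      st <- computeRestStats(bt, restThreshold = config@restThreshold,
                             window = window - tr@t0)
      st$genotype <- genotype(tr)
      st$condition <- schedule(tr)@label
      # periodogram over the post-pulse epoch only (free-running days)
      d <- distances(tr)
      from <- max(1L, as.integer(ceiling((window[1] - tr@t0) / tr@binWidth)) + 1L)
      sub <- d[from:length(d)]
      keep <- (length(sub) %/% 600L) * 600L
      track10 <- rebinActivity(
        ActivityTrack(sub[seq_len(keep)], binWidth = tr@binWidth,
                      animalId = animalId(tr), genotype = genotype(tr),
                      t0 = window[1], schedule = schedule(tr)), 600)
      call <- tryCatch({
        pg <- chiSquarePeriodogram(track10, periodRange = config@periodRange,
                                   alpha = config@alpha)
        classifyRhythmic(pg, animalId = animalId(tr))
      }, error = function(e) {
        # a flat (zero-variance) record has no defined periodogram; it is
        # an arrhythmic animal, not a pipeline failure
        if (!grepl("zero-variance", conditionMessage(e))) stop(e)
        new("RhythmCall", animalId = animalId(tr), isRhythmic = FALSE,
            peakPeriod = NA_real_, excess = NA_real_)
      })
      list(st = st, call = call)
    }, error = function(e)
      structure(list(reason = conditionMessage(e)), class = "pipelineFail"))
    if (inherits(res, "pipelineFail")) {
      fails[[length(fails) + 1L]] <-
        data.frame(animalId = animalId(tr), reason = res$reason,
                   stringsAsFactors = FALSE)
    } else {
      statsRows[[length(statsRows) + 1L]] <- res$st
      callRows[[length(callRows) + 1L]] <- res$call
    }
  }
  if (!length(statsRows))
    stop("no animal passed the behavior pipeline")
  statsTab <- do.call(rbind, statsRows)
  callTab <- rhythmCallTable(callRows,
    genotype = statsTab$genotype, condition = statsTab$condition)
  list(stats = statsTab,
       calls = callTab,
       ratios = rhythmicRatio(callTab),
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(animalId = character(0), reason = character(0)),
       manifest = list(config = configAsList(config), seed = config@seed,
                       nTracks = length(tracks),
                       nAnalyzed = nrow(statsTab),
                       version = as.character(
                         utils::packageVersion("circalarva"))))
}

#' Run the single-cell imaging pipeline on a set of traces
#'
#' For each cell: detrend (24-h centered moving average), normalize to
#' mean absolute intensity, fit the fixed-period cosinor, and extract the
#' phase.  Cells failing the zero-amplitude test at `alpha` are flagged
#' arrhythmic and listed, then excluded from the per-condition circular
#' summaries.
#'
#' @param traces list of [CellTrace-class] objects.
#' @param config an [AnalysisConfig-class].
#' @param period fixed cosinor period in hours (default 24).
#' @param detrendWindow moving-average window in hours (default 24).
#' @param nBins angular bins for the circular histograms (default 12).
#' @return list with `phases` (per-cell phase table), `summaries` (named
#'   list of [CircularSummary-class] per condition), `excluded` (cell ids
#'   flagged arrhythmic), and `manifest`.
#' @export
runImagingPipeline <- function(traces, config = AnalysisConfig(),
                               period = 24, detrendWindow = 24,
                               nBins = 12) {
  stopifnot(length(traces) >= 1)
  rows <- lapply(traces, function(tr) {
    proc <- normalizeTrace(detrendTrace(tr, windowH = detrendWindow),
                           mode = "mean")
    extractPhase(proc, period = period, alpha = config@alpha)
  })
  phases <- do.call(rbind, c(rows, make.row.names = FALSE))
  summaries <- list()
  for (cond in unique(phases$condition)) {
    sub <- phases[phases$condition == cond & phases$rhythmic, , drop = FALSE]
    if (nrow(sub) == 0)
      stop(sprintf("all cells in condition '%s' are arrhythmic", cond))
    if (nrow(sub) < 2)
      stop(sprintf(
        "condition '%s' has only %d rhythmic cell(s); >= 2 are required",
        cond, nrow(sub)))
    summaries[[cond]] <- circularSummary(sub$phase_rad, nBins = nBins)
  }
  list(phases = phases,
       summaries = summaries,
       excluded = phases$cellId[!phases$rhythmic],
       manifest = list(config = configAsList(config), seed = config@seed,
                       period = period, detrendWindow = detrendWindow,
                       nCells = length(traces),
                       nRhythmic = sum(phases$rhythmic),
                       version = as.character(
                         utils::packageVersion("circalarva"))))
}
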