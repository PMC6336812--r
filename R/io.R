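#' Column schema for tabular imports
#'
#' Tracking and imaging exports differ in column naming; a schema maps the
#' reader's required fields onto the file's column names.
#'
#' @param animal,genotype,time,distance column names for activity tables.
#' @param cell,condition,time_h,intensity column names for trace tables.
#' @param fillGaps zero-fill missing bins in activity tables instead of
#'   erroring (default `FALSE`: dense exports are expected and silent
#'   gap-fill corrupts bout lengths).
#' @return a named list used by [readActivityTable()] / [readTraceTable()].
#' @export
tableSchema <- function(animal = "animal_id", genotype = "genotype",
                        time = "time_s", distance = "distance_mm",
                        cell = "cell_id", condition = "condition",
                        time_h = "time_h", intensity = "intensity",
                        fillGaps = FALSE) {
  list(animal = animal, genotype = genotype, time = time,
       distance = distance, cell = cell, condition = condition,
       time_h = time_h, intensity = intensity, fillGaps = fillGaps)
}

.checkColumns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
}

.readCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(sprintf("file '%s' contains no data rows", path))
  df
}

.numericOrDie <- function(x, what, path) {
  if (is.numeric(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("non-numeric %s in '%s' at data row %d (value '%s')",
                 what, path, bad[1], x[bad[1]]))
  v
}

#' Read a long-format activity table
#'
#' One row per (animal, time-bin); columns per the schema.  Bins must form a
#' dense regular grid per animal unless `schema$fillGaps` is `TRUE`, in
#' which case missing bins are zero-filled.
#'
#' @param path CSV file path.
#' @param schema a [tableSchema()] list.
#' @param t0 recording start relative to light onset (s), applied to all
#'   animals.
#' @param schedule a [LightSchedule-class] applied to all animals.
#' @return named list of [ActivityTrack-class] objects.
#' @export
readActivityTable <- function(path, schema = tableSchema(), t0 = 0,
                              schedule = LightSchedule("DD")) {
  df <- .readCsv(path)
  .checkColumns(df, c(schema$animal, schema$genotype, schema$time,
                      schema$distance), path)
  df[[schema$time]] <- .numericOrDie(df[[schema$time]], "time", path)
  df[[schema$distance]] <- .numericOrDie(df[[schema$distance]],
                                         "distance", path)
  neg <- which(df[[schema$distance]] < 0)
  if (length(neg))
    stop(sprintf("negative distance in '%s' at data row %d", path, neg[1]))
  ids <- unique(df[[schema$animal]])
  tracks <- lapply(ids, function(id) {
    sub <- df[df[[schema$animal]] == id, , drop = FALSE]
    sub <- sub[order(sub[[schema$time]]), , drop = FALSE]
    tt <- sub[[schema$time]]
    if (anyDuplicated(tt))
      stop(sprintf("duplicate time bins for animal '%s' in '%s'", id, path))
    bw <- if (length(tt) > 1) min(diff(tt)) else 1
    grid <- seq(tt[1], tt[length(tt)], by = bw)
    d <- sub[[schema$distance]]
    if (length(grid) != length(tt) || any(abs(tt - grid) > 1e-9)) {
      if (!isTRUE(schema$fillGaps))
        stop(sprintf(
          "animal '%s' in '%s' has missing bins; set fillGaps = TRUE to zero-fill",
          id, path))
      full <- numeric(length(grid))
      full[round((tt - tt[1]) / bw) + 1] <- d
      d <- full
    }
    ActivityTrack(d, binWidth = bw, animalId = id,
                  genotype = sub[[schema$genotype]][1],
                  t0 = t0 + tt[1], schedule = schedule)
  })
  names(tracks) <- ids
  tracks
}

#' Write activity tracks to a long-format CSV
#'
#' @param tracks list of [ActivityTrack-class].
#' @param path output CSV path.
#' @param schema a [tableSchema()] list.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(tracks, path, schema = tableSchema()) {
  rows <- lapply(tracks, function(tr) {
    df <- data.frame(a = animalId(tr), g = genotype(tr),
                     t = (seq_along(distances(tr)) - 1) * binWidth(tr),
                     d = distances(tr))
    names(df) <- c(schema$animal, schema$genotype, schema$time,
                   schema$distance)
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format single-cell trace table
#'
#' One row per (cell, time); times are sorted per cell; duplicate
#' (cell, time) rows are an error.
#'
#' @param path CSV file path.
#' @param schema a [tableSchema()] list.
#' @return named list of [CellTrace-class] objects.
#' @export
readTraceTable <- function(path, schema = tableSchema()) {
  df <- .readCsv(path)
  .checkColumns(df, c(schema$cell, schema$condition, schema$time_h,
                      schema$intensity), path)
  df[[schema$time_h]] <- .numericOrDie(df[[schema$time_h]], "time", path)
  df[[schema$intensity]] <- .numericOrDie(df[[schema$intensity]],
                                          "intensity", path)
  ids <- unique(df[[schema$cell]])
  traces <- lapply(ids, function(id) {
    sub <- df[df[[schema$cell]] == id, , drop = FALSE]
    sub <- sub[order(sub[[schema$time_h]]), , drop = FALSE]
    if (anyDuplicated(sub[[schema$time_h]]))
      stop(sprintf("duplicate (cell, time) rows for cell '%s' in '%s'",
                   id, path))
    CellTrace(sub[[schema$time_h]], sub[[schema$intensity]], cellId = id,
              condition = sub[[schema$condition]][1])
  })
  names(traces) <- ids
  traces
}

#' Write cell traces to a long-format CSV
#'
#' @param traces list of [CellTrace-class].
#' @param path output CSV path.
#' @param schema a [tableSchema()] list.
#' @return `path`, invisibly.
#' @export
writeTraces <- function(traces, path, schema = tableSchema()) {
  rows <- lapply(traces, function(tr) {
    df <- data.frame(c = tr@cellId, k = tr@condition, t = tr@times,
                     i = tr@intensities)
    names(df) <- c(schema$cell, schema$condition, schema$time_h,
                   schema$intensity)
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read expression courses from a long-format CSV
#'
#' Columns `gene`, `time_h`, `value`; values renormalized to 1 at the
#' earliest timepoint.
#'
#' @param path CSV file path.
#' @return named list of [ExpressionCourse-class] objects.
#' @export
readExpressionTable <- function(path) {
  df <- .readCsv(path)
  .checkColumns(df, c("gene", "time_h", "value"), path)
  df$time_h <- .numericOrDie(df$time_h, "time", path)
  df$value <- .numericOrDie(df$value, "value", path)
  genes <- unique(df$gene)
  out <- lapply(genes, function(g) {
    sub <- df[df$gene == g, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    ExpressionCourse(sub$time_h, sub$value, gene = g)
  })
  names(out) <- genes
  out
}

#' Write expression courses to a long-format CSV
#'
#' @param courses list of [ExpressionCourse-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(courses, path) {
  rows <- lapply(courses, function(x)
    data.frame(gene = x@gene, time_h = x@times, value = x@values))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write result tables with a run-metadata manifest
#'
#' Each table becomes one CSV in `outDir`; a `run_metadata.json` file
#' records the configuration echo, seed, and per-file row counts and MD5
#' digests.  Data files are written deterministically: rewriting identical
#' input yields byte-identical CSVs.
#'
#' @param tables named list of data.frames.
#' @param outDir output directory (created if absent).
#' @param config optional [AnalysisConfig-class] echoed into the metadata.
#' @param seed optional seed echoed into the metadata.
#' @return data.frame manifest (file, rows, md5), invisibly.
#' @export
writeResults <- function(tables, outDir, config = NULL, seed = NULL) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop(sprintf("cannot create directory '%s'", outDir))
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    stop("tables must be a named list")
  files <- character(0); rows <- integer(0)
  for (nm in names(tables)) {
    f <- file.path(outDir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f); rows <- c(rows, nrow(tables[[nm]]))
  }
  md5 <- if (length(files)) unname(tools::md5sum(files)) else character(0)
  meta <- list(
    package = "circalarva",
    version = as.character(utils::packageVersion("circalarva")),
    seed = seed,
    config = if (!is.null(config)) configAsList(config) else NULL,
    files = if (length(files))
      data.frame(file = basename(files), rows = rows, md5 = md5)
    else NULL)
  jsonlite::write_json(meta, file.path(outDir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(data.frame(file = c(basename(files), "run_metadata.json"),
                       rows = c(rows, NA)))
}

#' Flatten an AnalysisConfig to a plain list
#' @param config an [AnalysisConfig-class].
#' @return named list of configuration values.
#' @export
configAsList <- function(config) {
  list(movementEpsilon = config@movementEpsilon,
       restThreshold = config@restThreshold,
       periodRange = config@periodRange, alpha = config@alpha,
       activityWindow = config@activityWindow, seed = config@seed)
}

#' Read an AnalysisConfig from JSON
#' @param path JSON file written by [writeConfig()].
#' @return an [AnalysisConfig-class].
#' @export
readConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  AnalysisConfig(movementEpsilon = x$movementEpsilon,
                 restThreshold = x$restThreshold,
                 periodRange = x$periodRange, alpha = x$alpha,
                 activityWindow = if (is.null(x$activityWindow)) NA_real_
                                  else x$activityWindow,
                 seed = x$seed)
}

#' Write an AnalysisConfig to JSON
#' @param config an [AnalysisConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(configAsList(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
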