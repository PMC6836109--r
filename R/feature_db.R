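#' Build a spectral feature database from centroided runs
#'
#' Extracts the empirical pools a simulation samples from: MS1 features
#' (one per ROI apex: m/z, RT, maximum intensity), MS2 peaks, per-scan
#' fragment counts, and scan durations keyed by the MS-level transition of
#' consecutive scans (the RT gap to the next scan in the same run; the
#' final scan of a run contributes nothing).
#'
#' @param runs A list of runs; each run is a list of scans (see
#'   [ms_scan()]) ordered by retention time.
#' @param min_intensity Intensity threshold applied both to ROI extraction
#'   (MS1 features) and to collected MS2 peaks.
#' @param roi_pars [roi_params()] used for MS1 feature extraction; its
#'   `min_point_intensity` is overridden by `min_intensity`.
#' @param formulas Optional character vector of molecular formulas to store
#'   alongside the spectral pools (synthetic sample workflow).
#' @return A `spectral_feature_db` object with fields `ms1_features` (data
#'   frame `mz`, `rt`, `max_intensity`), `ms2_peaks` (data frame `mz`,
#'   `intensity`), `fragment_counts` (integer vector), `scan_durations`
#'   (named list, keys `"1->1"`, `"1->2"`, `"2->1"`, `"2->2"`),
#'   `chromatograms` (list of [normalize_roi()] templates from the
#'   extracted ROIs) and `formulas`.
#' @export
build_feature_db <- function(runs, min_intensity = 0,
                             roi_pars = roi_params(), formulas = NULL) {
  if (length(runs) == 0L || all(vapply(runs, length, 1L) == 0L))
    stop("cannot build a spectral feature database from empty input")
  roi_pars$min_point_intensity <- min_intensity

  ms1 <- list(); chroms <- list()
  ms2_mz <- list(); ms2_int <- list(); frag_counts <- integer(0)
  durations <- list()

  for (run in runs) {
    levels <- vapply(run, function(s) as.integer(s$ms_level), 1L)
    rts <- vapply(run, function(s) as.numeric(s$rt), 1.0)

    rois <- extract_rois(run, roi_pars)
    for (r in rois) {
      apex <- which.max(r$intensity)
      ms1[[length(ms1) + 1L]] <- c(r$mz[apex], r$rt[apex], r$intensity[apex])
      chroms[[length(chroms) + 1L]] <- normalize_roi(r)
    }

    for (s in run[levels == 2L]) {
      keep <- s$intensity >= min_intensity
      frag_counts <- c(frag_counts, sum(keep))
      ms2_mz[[length(ms2_mz) + 1L]] <- s$mz[keep]
      ms2_int[[length(ms2_int) + 1L]] <- s$intensity[keep]
    }

    if (length(run) >= 2L) {
      for (i in seq_len(length(run) - 1L)) {
        key <- paste0(levels[i], "->", levels[i + 1L])
        durations[[key]] <- c(durations[[key]], rts[i + 1L] - rts[i])
      }
    }
  }

  if (length(frag_counts) == 0L)
    warning("no MS2 scans in input: MS2 peak and fragment-count pools are empty")

  ms1 <- if (length(ms1)) do.call(rbind, ms1) else
    matrix(numeric(0), ncol = 3)
  db <- structure(list(
    ms1_features = data.frame(mz = ms1[, 1], rt = ms1[, 2],
                              max_intensity = ms1[, 3]),
    ms2_peaks = data.frame(mz = unlist(ms2_mz, use.names = FALSE),
                           intensity = unlist(ms2_int, use.names = FALSE)),
    fragment_counts = as.integer(frag_counts),
    scan_durations = durations,
    chromatograms = chroms,
    formulas = formulas
  ), class = "spectral_feature_db")
  db
}

#' @export
print.spectral_feature_db <- function(x, ...) {
  cat("Spectral feature database\n")
  cat("  MS1 features:   ", nrow(x$ms1_features), "\n")
  cat("  MS2 peaks:      ", nrow(x$ms2_peaks), "\n")
  cat("  fragment counts:", length(x$fragment_counts), "scans\n")
  for (k in names(x$scan_durations))
    cat("  durations ", k, ": ", length(x$scan_durations[[k]]),
        " (median ", stats::median(x$scan_durations[[k]]), " s)\n", sep = "")
  cat("  chromatogram templates:", length(x$chromatograms), "\n")
  cat("  formulas:", length(x$formulas), "\n")
  invisible(x)
}

#' Sample uniformly from a feature-database pool
#'
#' Draws (with replacement) from one of the database pools. Reproducible
#' under `set.seed()`.
#'
#' @param db A `spectral_feature_db`.
#' @param kind One of `"ms1"`, `"ms2_peak"`, `"fragment_count"`.
#' @param n Number of draws.
#' @return For `"ms1"` and `"ms2_peak"`, a data frame of `n` sampled rows;
#'   for `"fragment_count"`, an integer vector.
#' @export
sample_feature <- function(db, kind = c("ms1", "ms2_peak", "fragment_count"),
                           n = 1L) {
  kind <- match.arg(kind)
  pool <- switch(kind, ms1 = db$ms1_features, ms2_peak = db$ms2_peaks,
                 fragment_count = db$fragment_counts)
  size <- if (is.data.frame(pool)) nrow(pool) else length(pool)
  if (size == 0L) stop("feature-database pool '", kind, "' is empty")
  idx <- sample.int(size, n, replace = TRUE)
  if (is.data.frame(pool)) pool[idx, , drop = FALSE] else pool[idx]
}

#' Sample a scan duration for a level transition
#'
#' Draws a duration from the pool recorded for the transition from
#' `prev_level` to `next_level`. If the transition was never observed (or
#' `prev_level` is `NA`, e.g. for the first scan of a run), falls back to
#' the pooled durations of all transitions into `next_level`.
#'
#' @param db A `spectral_feature_db`.
#' @param prev_level MS level of the previous scan (1, 2 or `NA`).
#' @param next_level MS level of the scan about to take place.
#' @return A duration in seconds.
#' @export
sample_scan_duration <- function(db, prev_level, next_level) {
  if (!is.na(prev_level)) {
    key <- paste0(prev_level, "->", next_level)
    pool <- db$scan_durations[[key]]
    if (length(pool))
      return(pool[sample.int(length(pool), 1L)])
    warning("no durations recorded for transition ", key,
            "; falling back to pooled level-", next_level, " durations",
            call. = FALSE)
  }
  suffix <- paste0("->", next_level)
  keys <- grep(suffix, names(db$scan_durations), fixed = TRUE, value = TRUE)
  pool <- unlist(db$scan_durations[keys], use.names = FALSE)
  if (!length(pool))
    stop("no scan durations available for MS level ", next_level)
  pool[sample.int(length(pool), 1L)]
}

.db_format_version <- "1.0"

#' Save or load a spectral feature database
#'
#' The database is persisted as a versioned JSON container with full double
#' precision, so that `read_feature_db(write_feature_db(db))` reproduces
#' every pool exactly.
#'
#' @param db A `spectral_feature_db`.
#' @param path File path (conventionally `.json`).
#' @return `write_feature_db` returns the path invisibly; `read_feature_db`
#'   returns the database.
#' @export
write_feature_db <- function(db, path) {
  payload <- list(
    format = "acquisim-feature-db",
    version = .db_format_version,
    ms1_features = db$ms1_features,
    ms2_peaks = db$ms2_peaks,
    fragment_counts = db$fragment_counts,
    scan_durations = db$scan_durations,
    chromatograms = lapply(db$chromatograms, function(ch)
      list(mz_offset = ch$mz_offset, rt_offset = ch$rt_offset,
           rel_intensity = ch$rel_intensity,
           apex_intensity = attr(ch, "apex_intensity"),
           apex_rt_offset = attr(ch, "apex_rt_offset"))),
    formulas = db$formulas
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_feature_db
#' @export
read_feature_db <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE),
                      error = function(e)
                        stop("cannot parse feature database at ", path,
                             ": ", conditionMessage(e)))
  if (!identical(payload$format, "acquisim-feature-db"))
    stop("not an acquisim feature database: ", path)
  chroms <- lapply(payload$chromatograms, function(ch)
    structure(data.frame(mz_offset = ch$mz_offset,
                         rt_offset = ch$rt_offset,
                         rel_intensity = ch$rel_intensity),
              apex_intensity = ch$apex_intensity,
              apex_rt_offset = ch$apex_rt_offset,
              class = c("normalized_roi", "data.frame")))
  structure(list(
    ms1_features = as.data.frame(payload$ms1_features),
    ms2_peaks = as.data.frame(payload$ms2_peaks),
    fragment_counts = as.integer(payload$fragment_counts),
    scan_durations = lapply(payload$scan_durations, as.numeric),
    chromatograms = chroms,
    formulas = if (length(payload$formulas)) as.character(payload$formulas)
  ), class = "spectral_feature_db")
}
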