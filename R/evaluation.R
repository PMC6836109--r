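#' Naive MS1 peak picker
#'
#' A bundled local-maximum picker intended for simulated data and tests:
#' ROIs are extracted from the MS1 scans of a log and every ROI whose apex
#' is at least `min_intensity` becomes a picked peak whose box is the ROI
#' extent (m/z range padded by `mz_pad` to give degenerate exact-mass
#' traces a usable width). Real analyses should import externally picked
#' peaks with [read_picked_peaks_csv()].
#'
#' @param scan_log A `scan_log` (or any list of `ms_scan`s).
#' @param params [roi_params()] for the extraction.
#' @param min_intensity Apex intensity threshold.
#' @param mz_pad Padding (Th) added on both sides of the ROI m/z range.
#' @return A data frame of picked peaks: `mz`, `mz_lo`, `mz_hi`, `rt_lo`,
#'   `rt_hi`, `apex_rt`, `apex_intensity`.
#' @export
pick_peaks <- function(scan_log, params = roi_params(),
                       min_intensity = 0, mz_pad = 0.01) {
  rois <- extract_rois(scan_log, params)
  rows <- lapply(rois, function(r) {
    apex <- which.max(r$intensity)
    if (r$intensity[apex] < min_intensity) return(NULL)
    data.frame(mz = mean(r$mz), mz_lo = min(r$mz) - mz_pad,
               mz_hi = max(r$mz) + mz_pad, rt_lo = min(r$rt),
               rt_hi = max(r$rt), apex_rt = r$rt[apex],
               apex_intensity = r$intensity[apex])
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    return(data.frame(mz = numeric(0), mz_lo = numeric(0),
                      mz_hi = numeric(0), rt_lo = numeric(0),
                      rt_hi = numeric(0), apex_rt = numeric(0),
                      apex_intensity = numeric(0)))
  do.call(rbind, rows)
}

#' Extract fragmentation events from a scan log
#'
#' @param scan_log A `scan_log`.
#' @return Data frame with one row per MS2 scan: `precursor_mz`, `rt`,
#'   `precursor_intensity`.
#' @export
fragmentation_events <- function(scan_log) {
  ms2 <- Filter(function(s) s$ms_level == 2L && !is.null(s$precursor),
                scan_log)
  data.frame(
    precursor_mz = vapply(ms2, function(s) s$precursor$mz, 1.0),
    rt = vapply(ms2, function(s) s$rt, 1.0),
    precursor_intensity = vapply(ms2, function(s) s$precursor$intensity,
                                 1.0)
  )
}

#' Flag picked peaks fragmented above a threshold
#'
#' A peak is flagged when at least one fragmentation event falls inside
#' its box (closed intervals on both the m/z and RT axes) with precursor
#' intensity at or above `min_intensity`.
#'
#' @param events Data frame from [fragmentation_events()] (columns
#'   `precursor_mz`, `rt`, `precursor_intensity`).
#' @param peaks Picked-peak data frame (columns `mz_lo`, `mz_hi`, `rt_lo`,
#'   `rt_hi`).
#' @param min_intensity Minimum qualifying precursor intensity.
#' @return Logical vector, one flag per peak.
#' @export
match_events <- function(events, peaks, min_intensity = 0) {
  if (!nrow(peaks)) return(logical(0))
  if (!nrow(events)) return(rep(FALSE, nrow(peaks)))
  ev <- events[events$precursor_intensity >= min_intensity, , drop = FALSE]
  vapply(seq_len(nrow(peaks)), function(i)
    any(ev$precursor_mz >= peaks$mz_lo[i] &
        ev$precursor_mz <= peaks$mz_hi[i] &
        ev$rt >= peaks$rt_lo[i] & ev$rt <= peaks$rt_hi[i]),
    TRUE)
}

#' Confusion counts for a fragmentation run
#'
#' Scores a DDA run against a full-scan run of the same sample. MS1
#' features picked from the two files are put in correspondence (m/z
#' centers within `match_ppm` parts per million and overlapping RT
#' ranges); features found in both files form the ground truth. With
#' "fragmented" meaning at least one fragmentation event inside the
#' feature box with precursor intensity at or above `min_intensity`:
#'
#' * TP: ground-truth features (both files) fragmented.
#' * FP: features only in the fragmentation file, fragmented.
#' * FN: features only in the full-scan file that are not fragmented
#'   (or fragmented below the threshold), plus ground-truth features that
#'   are not fragmented. The second group is an extension of the
#'   classical four-way split: without it, recall would ignore
#'   ground-truth features the strategy failed to fragment. Features only
#'   in the full-scan file that are fragmented above the threshold fall
#'   outside all four classes and are not counted.
#' * TN: features only in the fragmentation file, not fragmented.
#'
#' @param fullscan_peaks,frag_peaks Picked-peak data frames (see
#'   [pick_peaks()]) from the full-scan and fragmentation files.
#' @param events [fragmentation_events()] of the fragmentation run.
#' @param min_intensity Minimum qualifying precursor intensity.
#' @param match_ppm Cross-file m/z matching tolerance (ppm).
#' @return An `evaluation_counts` list: `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`, `undefined` (flags for 0/0 ratios,
#'   reported as 0).
#' @export
confusion_counts <- function(fullscan_peaks, frag_peaks, events,
                             min_intensity = 1.75e5, match_ppm = 10) {
  if (!nrow(fullscan_peaks))
    warning("empty full-scan peak list: no ground truth available")
  frag_matched <- .match_peak_sets(frag_peaks, fullscan_peaks, match_ppm)
  full_matched <- .match_peak_sets(fullscan_peaks, frag_peaks, match_ppm)
  frag_hit <- match_events(events, frag_peaks, min_intensity)
  full_hit <- match_events(events, fullscan_peaks, min_intensity)

  tp <- sum(frag_matched & frag_hit)
  fp <- sum(!frag_matched & frag_hit)
  tn <- sum(!frag_matched & !frag_hit)
  fn <- sum(!full_matched & !full_hit) + sum(frag_matched & !frag_hit)
  prf1(list(tp = tp, fp = fp, fn = fn, tn = tn))
}

## for each peak in `a`, is there a peak in `b` with m/z center within
## ppm tolerance and overlapping RT range?
.match_peak_sets <- function(a, b, ppm) {
  if (!nrow(a)) return(logical(0))
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i)
    any(abs(b$mz - a$mz[i]) <= a$mz[i] * ppm * 1e-6 &
        b$rt_lo <= a$rt_hi[i] & b$rt_hi >= a$rt_lo[i]),
    TRUE)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Ratios with a
#' zero denominator are reported as 0 and flagged in `undefined`.
#'
#' @param counts A list with non-negative `tp`, `fp`, `fn` (and
#'   optionally `tn`).
#' @return An `evaluation_counts` list (see [confusion_counts()]).
#' @export
prf1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  tn <- if (is.null(counts$tn)) NA_integer_ else counts$tn
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); 0
  }
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall)
  else {
    undefined <- c(undefined, "f1"); 0
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1,
                 undefined = undefined),
            class = "evaluation_counts")
}

#' @export
print.evaluation_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %s\n", x$tp, x$fp, x$fn,
              ifelse(is.na(x$tn), "-", x$tn)))
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  if (length(x$undefined))
    cat("undefined (0/0, reported as 0):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate Top-N acquisition over a parameter grid
#'
#' Runs one full-scan MS1 acquisition of the sample as reference, then one
#' Top-N simulation per `(N, dew)` combination, picks MS1 features from
#' both files with the naive picker, and scores each cell with
#' [confusion_counts()].
#'
#' @param chemicals Chemical list defining the sample.
#' @param db A `spectral_feature_db`.
#' @param n_values,dew_values Grid of Top-N sizes and dynamic exclusion
#'   windows (s).
#' @param start_rt,end_rt Acquisition window (s).
#' @param params Baseline [top_n_params()]; `N` and `dew` are overridden
#'   per cell.
#' @param picker_params [roi_params()] for peak picking.
#' @param duration_fn Optional fixed-timing override, see [virtual_ms()].
#' @return Data frame with one row per grid cell: `N`, `dew`, `tp`, `fp`,
#'   `fn`, `tn`, `precision`, `recall`, `f1`, `peaks_picked` (MS1 features
#'   found in the fragmentation file) and `n_ms1_scans`.
#' @export
grid_evaluate <- function(chemicals, db, n_values, dew_values,
                          start_rt, end_rt, params = top_n_params(),
                          picker_params = roi_params(),
                          duration_fn = NULL) {
  if (!length(n_values) || !length(dew_values))
    return(data.frame(N = numeric(0), dew = numeric(0)))
  full_log <- run_acquisition(chemicals, ms1_controller(), db,
                              start_rt, end_rt, duration_fn)
  full_peaks <- pick_peaks(full_log, picker_params)

  rows <- list()
  for (dew in dew_values) {
    for (N in n_values) {
      p <- params; p$N <- N; p$dew <- dew
      log <- run_acquisition(chemicals, top_n_controller(p), db,
                             start_rt, end_rt, duration_fn)
      frag_peaks <- pick_peaks(log, picker_params)
      ev <- fragmentation_events(log)
      cc <- confusion_counts(full_peaks, frag_peaks, ev,
                             p$min_ms1_intensity)
      lv <- vapply(log, `[[`, 1L, "ms_level")
      rows[[length(rows) + 1L]] <- data.frame(
        N = N, dew = dew, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
        precision = cc$precision, recall = cc$recall, f1 = cc$f1,
        peaks_picked = nrow(frag_peaks), n_ms1_scans = sum(lv == 1L))
    }
  }
  do.call(rbind, rows)
}

#' Multi-sample fragmentation coverage
#'
#' Counts how many aligned peaks have at least one qualifying
#' fragmentation event (inside the peak box, precursor intensity at or
#' above `min_intensity`) in any sample.
#'
#' @param aligned_peaks Picked/aligned peak data frame (columns `mz_lo`,
#'   `mz_hi`, `rt_lo`, `rt_hi`).
#' @param events Fragmentation events pooled over all samples.
#' @param min_intensity Minimum qualifying precursor intensity.
#' @return Integer count.
#' @export
coverage_count <- function(aligned_peaks, events, min_intensity = 1.75e5)
  sum(match_events(events, aligned_peaks, min_intensity))

#' Read or write picked peaks as CSV
#'
#' The interchange format for externally picked peak lists: columns
#' `mz_lo`, `mz_hi`, `rt_lo`, `rt_hi`, `apex_intensity` (extra columns
#' are preserved; `mz`, `apex_rt` are reconstructed if absent).
#'
#' @param path CSV path.
#' @param peaks Picked-peak data frame.
#' @return `read_picked_peaks_csv` returns the data frame;
#'   `write_picked_peaks_csv` returns the path invisibly.
#' @export
read_picked_peaks_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("mz_lo", "mz_hi", "rt_lo", "rt_hi", "apex_intensity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("picked-peak CSV lacks column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(df$mz)) df$mz <- (df$mz_lo + df$mz_hi) / 2
  if (is.null(df$apex_rt)) df$apex_rt <- (df$rt_lo + df$rt_hi) / 2
  df
}

#' @rdname read_picked_peaks_csv
#' @export
write_picked_peaks_csv <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}
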