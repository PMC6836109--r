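#' Region-of-interest extraction parameters
#'
#' Parameters controlling how mass traces are grouped into regions of
#' interest (ROIs) across consecutive centroided MS1 scans.
#'
#' @param mz_tol_ppm Mass tolerance window in parts per million, applied
#'   above and below the running mean m/z of an ROI.
#' @param min_point_intensity Points below this intensity are ignored.
#' @param min_points ROIs with fewer points than this are discarded.
#' @return An object of class `roi_params`.
#' @export
roi_params <- function(mz_tol_ppm = 10, min_point_intensity = 0,
                       min_points = 3) {
  stopifnot(mz_tol_ppm > 0, min_point_intensity >= 0, min_points >= 1)
  structure(list(mz_tol_ppm = mz_tol_ppm,
                 min_point_intensity = min_point_intensity,
                 min_points = min_points),
            class = "roi_params")
}

#' Extract regions of interest from centroided MS1 scans
#'
#' Loops over RT-ordered scans and groups centroids into ROIs: each point is
#' matched to the open ROI whose running mean m/z lies within
#' `mz_tol_ppm` of the point (closest mean wins; ties go to the
#' earlier-created ROI). An ROI accepts at most one point per scan; when two
#' points in one scan match the same ROI the closer one joins and the other
#' seeds a new ROI. ROIs not extended in a scan are closed. ROIs with fewer
#' than `min_points` points are discarded.
#'
#' @param scans A list of scans (see [ms_scan()]); only level-1 scans are
#'   used. Scans must be ordered by retention time.
#' @param params An [roi_params()] object.
#' @param all If `TRUE`, return a list with elements `kept` and `discarded`
#'   (the latter holding ROIs that failed the `min_points` filter) rather
#'   than just the kept ROIs.
#' @return A list of `roi` objects (data frames with columns `mz`, `rt`,
#'   `intensity`), ordered by creation.
#' @export
extract_rois <- function(scans, params = roi_params(), all = FALSE) {
  stopifnot(inherits(params, "roi_params"))
  ms1 <- Filter(function(s) is.null(s$ms_level) || s$ms_level == 1L, scans)
  tol <- params$mz_tol_ppm * 1e-6

  ## open ROI state (parallel vectors / lists)
  o_mz <- list(); o_rt <- list(); o_int <- list()
  o_sum <- numeric(0); o_n <- integer(0); o_id <- integer(0)
  closed <- list()
  next_id <- 1L

  close_rois <- function(idx) {
    for (k in idx)
      closed[[length(closed) + 1L]] <<- list(mz = o_mz[[k]], rt = o_rt[[k]],
                                             intensity = o_int[[k]])
    keep <- setdiff(seq_along(o_sum), idx)
    o_mz <<- o_mz[keep]; o_rt <<- o_rt[keep]; o_int <<- o_int[keep]
    o_sum <<- o_sum[keep]; o_n <<- o_n[keep]; o_id <<- o_id[keep]
  }

  for (s in ms1) {
    keep_p <- which(s$intensity >= params$min_point_intensity)
    pmz <- s$mz[keep_p]; pint <- s$intensity[keep_p]
    ord <- order(pmz); pmz <- pmz[ord]; pint <- pint[ord]
    np <- length(pmz); nr <- length(o_sum)
    extended <- logical(nr)
    assigned <- integer(np)  # 0 = unassigned

    if (np > 0L && nr > 0L) {
      means <- o_sum / o_n
      d <- abs(outer(pmz, means, "-"))           # np x nr
      elig <- d <= outer(rep(1, np), means * tol)
      if (any(elig)) {
        idx <- which(elig)
        pi <- ((idx - 1L) %% np) + 1L
        ri <- ((idx - 1L) %/% np) + 1L
        ord2 <- order(d[idx], o_id[ri], pmz[pi])
        for (k in ord2) {
          p <- pi[k]; r <- ri[k]
          if (assigned[p] == 0L && !extended[r]) {
            assigned[p] <- r
            extended[r] <- TRUE
          }
        }
      }
    }

    if (np > 0L) {
      for (p in seq_len(np)) {
        r <- assigned[p]
        if (r > 0L) {
          o_mz[[r]] <- c(o_mz[[r]], pmz[p])
          o_rt[[r]] <- c(o_rt[[r]], s$rt)
          o_int[[r]] <- c(o_int[[r]], pint[p])
          o_sum[r] <- o_sum[r] + pmz[p]
          o_n[r] <- o_n[r] + 1L
        } else {
          o_mz[[length(o_mz) + 1L]] <- pmz[p]
          o_rt[[length(o_rt) + 1L]] <- s$rt
          o_int[[length(o_int) + 1L]] <- pint[p]
          o_sum <- c(o_sum, pmz[p]); o_n <- c(o_n, 1L)
          o_id <- c(o_id, next_id); next_id <- next_id + 1L
        }
      }
      extended <- c(extended, rep(TRUE, length(o_sum) - length(extended)))
    }
    if (length(o_sum)) close_rois(which(!extended))
  }
  close_rois(seq_along(o_sum))

  rois <- lapply(closed, function(x)
    structure(data.frame(mz = x$mz, rt = x$rt, intensity = x$intensity),
              class = c("roi", "data.frame")))
  npoints <- vapply(rois, nrow, 1L)
  kept <- rois[npoints >= params$min_points]
  if (all)
    list(kept = kept, discarded = rois[npoints < params$min_points])
  else
    kept
}

#' Normalize an ROI into a reusable chromatogram template
#'
#' Centers m/z values on the ROI mean, shifts retention times to start at
#' zero, and scales intensities to a maximum of one, so the trace can be
#' assigned to a chemical object as its chromatographic shape.
#'
#' @param roi An `roi` data frame (columns `mz`, `rt`, `intensity`).
#' @return A `normalized_roi` data frame with columns `mz_offset`,
#'   `rt_offset`, `rel_intensity`, and attributes `apex_intensity` (the
#'   source ROI's maximum intensity) and `apex_rt_offset`.
#' @export
normalize_roi <- function(roi) {
  stopifnot(nrow(roi) >= 1L)
  mx <- max(roi$intensity)
  if (mx <= 0) stop("cannot normalize an ROI with no positive intensity")
  apex <- which.max(roi$intensity)
  structure(data.frame(mz_offset = roi$mz - mean(roi$mz),
                       rt_offset = roi$rt - roi$rt[1L],
                       rel_intensity = roi$intensity / mx),
            apex_intensity = mx,
            apex_rt_offset = roi$rt[apex] - roi$rt[1L],
            class = c("normalized_roi", "data.frame"))
}

#' Write ROIs to a CSV file
#'
#' @param rois A list of `roi` objects from [extract_rois()].
#' @param path Output CSV path; columns `roi_id`, `mz`, `rt`, `intensity`.
#' @return The path, invisibly.
#' @export
write_rois_csv <- function(rois, path) {
  df <- do.call(rbind, lapply(seq_along(rois), function(i)
    cbind(roi_id = i, as.data.frame(rois[[i]]))))
  if (is.null(df)) df <- data.frame(roi_id = integer(0), mz = numeric(0),
                                    rt = numeric(0), intensity = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
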