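#' Full-scan MS1 controller
#'
#' Requests level-1 scans for the whole acquisition window; the scan
#' timing comes from the virtual mass spectrometer's duration source.
#'
#' @return A controller usable with [run_acquisition()].
#' @export
ms1_controller <- function() {
  structure(list(
    next_request = function(rt) list(ms_level = 1L),
    scan_done = function(scan) invisible(NULL)
  ), class = "controller")
}

#' Top-N DDA parameters
#'
#' @param N Maximum number of fragmentation scans per duty cycle.
#' @param dew Dynamic exclusion window (s): after a precursor is
#'   fragmented its m/z may not be selected again until this much time has
#'   passed.
#' @param min_ms1_intensity Minimum MS1 intensity for a precursor to be
#'   selected.
#' @param isolation_width Width of the isolation window (Th) centered on
#'   the precursor m/z.
#' @param mz_tol Absolute m/z tolerance (Th) used when matching a
#'   candidate precursor against exclusion records (and between precursors
#'   selected in the same cycle).
#' @return An object of class `top_n_params`.
#' @export
top_n_params <- function(N = 10, dew = 15, min_ms1_intensity = 1.75e5,
                         isolation_width = 1.0, mz_tol = 0.01) {
  stopifnot(N >= 0, dew >= 0, isolation_width > 0, mz_tol >= 0)
  structure(list(N = N, dew = dew, min_ms1_intensity = min_ms1_intensity,
                 isolation_width = isolation_width, mz_tol = mz_tol),
            class = "top_n_params")
}

#' Select the Top-N precursors from an MS1 scan
#'
#' Orders peaks by descending intensity (ties broken by lower m/z),
#' removes peaks below the minimum MS1 intensity, peaks matching an active
#' exclusion record within `mz_tol`, and peaks within `mz_tol` of an
#' already-selected precursor, and returns at most `N` precursors.
#'
#' @param peaks An `ms_scan` or a data frame with columns `mz`,
#'   `intensity`.
#' @param params A [top_n_params()].
#' @param exclusions Data frame of exclusion records (`mz`, `expiry_rt`),
#'   or `NULL`.
#' @param rt Current RT (s) against which exclusion expiries are checked.
#' @return Data frame of selected precursors (`mz`, `intensity`),
#'   descending intensity.
#' @export
select_top_n <- function(peaks, params, exclusions = NULL, rt = 0) {
  mz <- peaks$mz; int <- peaks$intensity
  keep <- int >= params$min_ms1_intensity
  mz <- mz[keep]; int <- int[keep]
  o <- order(-int, mz)
  mz <- mz[o]; int <- int[o]
  ex_mz <- if (!is.null(exclusions))
    exclusions$mz[exclusions$expiry_rt > rt] else numeric(0)
  sel_mz <- numeric(0); sel_int <- numeric(0)
  for (i in seq_along(mz)) {
    if (length(sel_mz) >= params$N) break
    m <- mz[i]
    if (length(ex_mz) && any(abs(ex_mz - m) <= params$mz_tol)) next
    if (length(sel_mz) && any(abs(sel_mz - m) <= params$mz_tol)) next
    sel_mz <- c(sel_mz, m); sel_int <- c(sel_int, int[i])
  }
  data.frame(mz = sel_mz, intensity = sel_int)
}

#' Top-N DDA controller with dynamic exclusion
#'
#' Implements the standard DDA duty cycle: a survey MS1 scan, then up to
#' `N` MS2 scans on the most intense eligible precursors, with a dynamic
#' exclusion window preventing a precursor m/z from being fragmented again
#' within `dew` seconds of its last fragmentation. Precursors are selected
#' on their survey-scan intensity; the intensity recorded in each MS2 scan
#' is the one the virtual MS measures when the fragmentation scan actually
#' executes, which may have decayed below the selection threshold by the
#' end of a long duty cycle.
#'
#' @param params A [top_n_params()].
#' @return A controller usable with [run_acquisition()].
#' @export
top_n_controller <- function(params) {
  stopifnot(inherits(params, "top_n_params"))
  e <- new.env(parent = emptyenv())
  e$queue <- list()
  e$ex_mz <- numeric(0)
  e$ex_expiry <- numeric(0)

  scan_done <- function(scan) {
    if (scan$ms_level == 1L) {
      alive <- e$ex_expiry > scan$rt
      e$ex_mz <- e$ex_mz[alive]; e$ex_expiry <- e$ex_expiry[alive]
      sel <- select_top_n(scan, params,
                          data.frame(mz = e$ex_mz, expiry_rt = e$ex_expiry),
                          scan$rt)
      ## the recorded precursor intensity is measured by the virtual MS
      ## when the fragmentation scan executes (it may have decayed below
      ## the selection threshold by then); selection-time intensity is
      ## only used for ordering here
      e$queue <- lapply(seq_len(nrow(sel)), function(i)
        list(ms_level = 2L,
             precursor_mz = sel$mz[i],
             isolation = sel$mz[i] +
               c(-0.5, 0.5) * params$isolation_width,
             parent_scan = scan$scan_id))
    } else {
      e$ex_mz <- c(e$ex_mz, scan$precursor$mz)
      e$ex_expiry <- c(e$ex_expiry, scan$rt + params$dew)
    }
    invisible(NULL)
  }

  next_request <- function(rt) {
    if (length(e$queue)) {
      req <- e$queue[[1L]]
      e$queue <- e$queue[-1L]
      req
    } else list(ms_level = 1L)
  }

  structure(list(next_request = next_request, scan_done = scan_done,
                 state = e), class = "controller")
}

#' Controller replaying a fixed schedule of scan requests
#'
#' Executes a precomputed request list in order (used by the
#' data-set-dependent acquisition scheduler, which plans the next sample's
#' scans from the previous samples' results); once the schedule is
#' exhausted it falls back to MS1 scans.
#'
#' @param requests A list of scan-request lists.
#' @return A controller usable with [run_acquisition()].
#' @export
scheduled_controller <- function(requests) {
  e <- new.env(parent = emptyenv())
  e$i <- 0L
  e$requests <- requests
  structure(list(
    next_request = function(rt) {
      e$i <- e$i + 1L
      if (e$i <= length(e$requests)) e$requests[[e$i]]
      else list(ms_level = 1L)
    },
    scan_done = function(scan) invisible(NULL),
    state = e
  ), class = "controller")
}

#' DsDA feature priority weights
#'
#' Features with high MS1 intensity that are unfragmented (quality 0) or
#' poorly fragmented get the highest weight:
#' `weight = intensity * (1 - quality)`.
#'
#' @param intensity Maximum observed MS1 intensity per feature.
#' @param quality Best MS2 spectrum quality per feature, in `[0, 1]`
#'   (0 for unfragmented features).
#' @return Non-negative weights.
#' @export
dsda_priority <- function(intensity, quality) {
  stopifnot(all(quality >= 0 & quality <= 1), all(intensity >= 0))
  intensity * (1 - quality)
}

## MS2 spectrum quality surrogate: fraction of a reference fragment count
## observed above a noise floor, capped at 1.
.ms2_quality <- function(scan, k_ref, noise_floor)
  min(1, sum(scan$intensity >= noise_floor) / k_ref)

#' Data-set-dependent acquisition over multiple samples
#'
#' Acquires an ordered series of related samples. The first sample is run
#' with the Top-N controller on a fixed timing schedule (constant MS1 and
#' MS2 durations set to the medians of the feature database pools). After
#' each sample, MS1 features are picked from its scans with the bundled
#' naive picker and merged into a cross-sample feature registry; each
#' feature's best MS2 quality is updated from the fragmentation events
#' that hit it (events whose measured precursor intensity falls below the
#' picking threshold are ignored, so uselessly fragmented features stay
#' schedulable), and priority weights are recomputed with
#' [dsda_priority()]. The next sample is then planned by walking the
#' clock over the fixed timing grid: each cycle opens with an MS1 scan
#' and fragments up to `N` positive-weight features whose RT boxes
#' contain the current time - highest weight first (weighted-randomly
#' when `max_depth` is on), one slot per feature per sample; when no
#' eligible feature remains the cycle returns early to MS1. Scheduled
#' MS2 scans record the precursor intensity actually measured in the
#' isolation window at execution time.
#'
#' @param samples List of chemical lists (one per sample, in acquisition
#'   order).
#' @param db A `spectral_feature_db`.
#' @param params A [top_n_params()]; `N = 4` is the conventional default
#'   for this strategy.
#' @param start_rt,end_rt Acquisition window (s).
#' @param max_depth If `TRUE`, slot assignment uses weighted-random
#'   ordering instead of greedy, boosting rare low-weight features.
#' @param quality_k Reference fragment-peak count at which an MS2 spectrum
#'   counts as full quality.
#' @param noise_floor Fragment peaks below this intensity are ignored by
#'   the quality surrogate.
#' @param picker_params [roi_params()] for the between-sample peak picker.
#' @param picker_min_intensity Apex threshold for picked features.
#' @return A list with `scan_logs` (one `scan_log` per sample) and
#'   `registry` (the final feature registry with weights).
#' @export
dsda_run <- function(samples, db, params = top_n_params(N = 4),
                     start_rt, end_rt, max_depth = FALSE,
                     quality_k = 10, noise_floor = 0,
                     picker_params = roi_params(),
                     picker_min_intensity = params$min_ms1_intensity) {
  stopifnot(length(samples) >= 1L)
  d1 <- stats::median(unlist(db$scan_durations[
    grep("->1", names(db$scan_durations), fixed = TRUE)]))
  d2 <- stats::median(unlist(db$scan_durations[
    grep("->2", names(db$scan_durations), fixed = TRUE)]))
  if (!is.finite(d2)) d2 <- d1
  duration_fn <- function(prev, nxt) if (nxt == 1L) d1 else d2

  if (params$N < 1)
    warning("no MS2 slots in the timing grid; schedules are MS1-only")

  registry <- data.frame(mz = numeric(0), mz_lo = numeric(0),
                         mz_hi = numeric(0), rt_lo = numeric(0),
                         rt_hi = numeric(0), apex_rt = numeric(0),
                         apex_intensity = numeric(0), quality = numeric(0))
  logs <- vector("list", length(samples))

  for (s in seq_along(samples)) {
    if (s == 1L) {
      ctl <- top_n_controller(params)
    } else {
      ctl <- scheduled_controller(
        .dsda_schedule(registry, params, d1, d2, start_rt, end_rt,
                       max_depth))
    }
    log <- run_acquisition(samples[[s]], ctl, db, start_rt, end_rt,
                           duration_fn)
    logs[[s]] <- log

    picked <- pick_peaks(log, picker_params, picker_min_intensity)
    registry <- .merge_registry(registry, picked)

    for (scan in log) {
      if (scan$ms_level != 2L || is.null(scan$precursor)) next
      ## a spectrum acquired from a precursor measured below the picking
      ## threshold is not evidence of coverage: leave quality untouched
      ## so the feature stays schedulable
      if (scan$precursor$intensity < picker_min_intensity) next
      hit <- which(scan$precursor$mz >= registry$mz_lo &
                   scan$precursor$mz <= registry$mz_hi &
                   scan$rt >= registry$rt_lo & scan$rt <= registry$rt_hi)
      if (length(hit)) {
        q <- .ms2_quality(scan, quality_k, noise_floor)
        registry$quality[hit] <- pmax(registry$quality[hit], q)
      }
    }
  }
  registry$weight <- dsda_priority(registry$apex_intensity,
                                   registry$quality)
  list(scan_logs = logs, registry = registry)
}

## Build the next sample's schedule by walking the acquisition clock.
## Scan durations under the fixed timing grid are known (d1 for MS1, d2
## for MS2), so planned and executed scan times coincide exactly. Each
## cycle starts with an MS1 scan; up to N fragmentation scans follow,
## each given to the positive-weight feature of highest weight currently
## near its apex (weighted-random among eligible when max_depth is on),
## one slot per feature per sample. When no eligible feature remains the
## cycle ends early, returning time to MS1. Eligibility requires the
## clock to be within one sixth of the feature's RT extent of its apex:
## for a peak spanning +/- 3 sigma that is the +/- 1 sigma core, where
## the signal still carries most of its apex intensity - fragmenting at
## the box edges would produce spectra too weak to count.
.dsda_schedule <- function(registry, params, d1, d2, start_rt, end_rt,
                           max_depth) {
  N <- params$N
  if (N < 1 || nrow(registry) == 0L) return(list())
  w <- dsda_priority(registry$apex_intensity, registry$quality)
  core <- pmax((registry$rt_hi - registry$rt_lo) / 6, d2)
  assigned <- rep(FALSE, nrow(registry))
  reqs <- list()
  t <- start_rt
  while (t < end_rt) {
    reqs[[length(reqs) + 1L]] <- list(ms_level = 1L)
    t <- t + d1
    for (j in seq_len(N)) {
      if (t >= end_rt) break
      elig <- which(!assigned & w > 0 &
                    abs(t - registry$apex_rt) <= core)
      if (!length(elig)) break
      f <- if (max_depth && length(elig) > 1L) {
        elig[sample.int(length(elig), 1L, prob = w[elig])]
      } else {
        elig[order(-w[elig], abs(registry$apex_rt[elig] - t))[1L]]
      }
      assigned[f] <- TRUE
      reqs[[length(reqs) + 1L]] <- list(
        ms_level = 2L, precursor_mz = registry$mz[f],
        isolation = registry$mz[f] +
          c(-0.5, 0.5) * params$isolation_width)
      t <- t + d2
    }
  }
  reqs
}

## merge newly picked features into the cross-sample registry
## (match: m/z centers within 10 ppm and overlapping RT ranges)
.merge_registry <- function(registry, picked, ppm = 10) {
  if (!nrow(picked)) return(registry)
  for (i in seq_len(nrow(picked))) {
    m <- picked$mz[i]
    hit <- which(abs(registry$mz - m) <= registry$mz * ppm * 1e-6 &
                 picked$rt_lo[i] <= registry$rt_hi &
                 picked$rt_hi[i] >= registry$rt_lo)
    if (length(hit)) {
      h <- hit[which.min(abs(registry$mz[hit] - m))]
      if (picked$apex_intensity[i] > registry$apex_intensity[h])
        registry$apex_intensity[h] <- picked$apex_intensity[i]
      registry$rt_lo[h] <- min(registry$rt_lo[h], picked$rt_lo[i])
      registry$rt_hi[h] <- max(registry$rt_hi[h], picked$rt_hi[i])
    } else {
      registry <- rbind(registry, data.frame(
        mz = m, mz_lo = picked$mz_lo[i], mz_hi = picked$mz_hi[i],
        rt_lo = picked$rt_lo[i], rt_hi = picked$rt_hi[i],
        apex_rt = picked$apex_rt[i],
        apex_intensity = picked$apex_intensity[i], quality = 0))
    }
  }
  registry
}
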