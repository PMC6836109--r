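#' Construct a scan
#'
#' The basic container for a simulated (or loaded) centroided scan.
#'
#' @param scan_id Integer scan number.
#' @param ms_level 1 or 2.
#' @param rt Retention time (s) at scan start.
#' @param duration Scan duration (s).
#' @param mz,intensity Centroid arrays, sorted by m/z.
#' @param precursor For MS2 scans, a list with `mz`, `intensity` and
#'   `scan_id` of the triggering MS1 scan.
#' @param isolation For MS2 scans, the isolation window `c(lo, hi)` in Th.
#' @return A list of class `ms_scan`.
#' @export
ms_scan <- function(scan_id, ms_level, rt, duration, mz, intensity,
                    precursor = NULL, isolation = NULL) {
  o <- order(mz)
  structure(list(scan_id = as.integer(scan_id),
                 ms_level = as.integer(ms_level),
                 rt = rt, duration = duration,
                 mz = mz[o], intensity = intensity[o],
                 precursor = precursor, isolation = isolation),
            class = "ms_scan")
}

#' @export
print.ms_scan <- function(x, ...) {
  cat(sprintf("MS%d scan #%d @ %.2f s (%.3f s), %d peaks",
              x$ms_level, x$scan_id, x$rt, x$duration, length(x$mz)))
  if (!is.null(x$precursor))
    cat(sprintf(", precursor %.4f", x$precursor$mz))
  cat("\n")
  invisible(x)
}

#' Interpolate a chromatogram template at an RT offset
#'
#' Linear interpolation between the two nearest stored points of a
#' normalized chromatogram; at a stored point the stored values are
#' returned exactly, and outside the template's RT span the signal is
#' zero.
#'
#' @param chromatogram A `normalized_roi`.
#' @param rt_offset RT offset (s) from the chromatogram start.
#' @return Named numeric vector `c(rel_intensity, mz_offset)`.
#' @export
interpolate_signal <- function(chromatogram, rt_offset) {
  rt <- chromatogram$rt_offset
  n <- length(rt)
  if (rt_offset < rt[1L] || rt_offset > rt[n])
    return(c(rel_intensity = 0, mz_offset = 0))
  j <- findInterval(rt_offset, rt)
  if (j == n || rt_offset == rt[j])
    return(c(rel_intensity = chromatogram$rel_intensity[j],
             mz_offset = chromatogram$mz_offset[j]))
  w <- (rt_offset - rt[j]) / (rt[j + 1L] - rt[j])
  c(rel_intensity = (1 - w) * chromatogram$rel_intensity[j] +
      w * chromatogram$rel_intensity[j + 1L],
    mz_offset = (1 - w) * chromatogram$mz_offset[j] +
      w * chromatogram$mz_offset[j + 1L])
}

#' Create a virtual mass spectrometer
#'
#' Holds the simulation state: the chemicals (pre-expanded into MS1
#' traces), the clock, the scan log, and the scan-duration source. Scan
#' requests are answered by [generate_scan()]; a whole acquisition is
#' driven by [run_acquisition()].
#'
#' @param chemicals List of chemical objects.
#' @param db A `spectral_feature_db` supplying scan durations.
#' @param start_rt,end_rt Acquisition window (s).
#' @param duration_fn Optional `function(prev_level, next_level)`
#'   overriding empirical duration sampling (used for fixed timing
#'   schedules).
#' @return An environment of class `virtual_ms`.
#' @export
virtual_ms <- function(chemicals, db, start_rt, end_rt,
                       duration_fn = NULL) {
  stopifnot(start_rt < end_rt)
  n <- length(chemicals)
  e <- new.env(parent = emptyenv())
  e$db <- db
  e$duration_fn <- duration_fn
  e$clock <- start_rt
  e$start_rt <- start_rt
  e$end_rt <- end_rt
  e$prev_level <- NA_integer_
  e$scans <- vector("list", 512L)
  e$n_scans <- 0L
  e$last_ms1_id <- NA_integer_

  ## chemical-level arrays
  e$chemicals <- chemicals
  e$chem_start <- vapply(chemicals, function(c) c$start_rt, 1.0)
  e$chem_end <- e$chem_start +
    vapply(chemicals, function(c) max(c$chromatogram$rt_offset), 1.0)
  e$chem_max <- vapply(chemicals, function(c) c$max_intensity, 1.0)
  e$knots <- lapply(seq_len(n), function(i)
    e$chem_start[i] + chemicals[[i]]$chromatogram$rt_offset)
  e$rel <- lapply(chemicals, function(c) c$chromatogram$rel_intensity)
  e$mzo <- lapply(chemicals, function(c) c$chromatogram$mz_offset)

  ## trace-level arrays
  traces <- lapply(chemicals, chemical_traces)
  e$trace_mz <- unlist(lapply(traces, `[[`, "base_mz"), use.names = FALSE)
  e$trace_prop <- unlist(lapply(traces, `[[`, "proportion"),
                         use.names = FALSE)
  nt <- vapply(traces, nrow, 1L)
  e$trace_chem <- rep(seq_len(n), nt)
  ends <- cumsum(nt)
  e$traces_by_chem <- lapply(seq_len(n), function(i)
    if (nt[i]) (ends[i] - nt[i] + 1L):ends[i] else integer(0))
  class(e) <- "virtual_ms"
  e
}

## interpolate all active traces at time t; returns trace indices with
## their current m/z and intensity
.eluting_traces <- function(vms, t) {
  act <- which(vms$chem_start <= t & t <= vms$chem_end)
  if (!length(act))
    return(list(trace = integer(0), chem = integer(0),
                mz = numeric(0), intensity = numeric(0)))
  k <- length(act)
  rel <- numeric(k); mzo <- numeric(k)
  for (i in seq_len(k)) {
    ci <- act[i]
    kn <- vms$knots[[ci]]
    j <- findInterval(t, kn)
    nn <- length(kn)
    if (j >= nn || t == kn[j]) {
      jj <- min(j, nn)
      rel[i] <- vms$rel[[ci]][jj]; mzo[i] <- vms$mzo[[ci]][jj]
    } else {
      w <- (t - kn[j]) / (kn[j + 1L] - kn[j])
      rel[i] <- (1 - w) * vms$rel[[ci]][j] + w * vms$rel[[ci]][j + 1L]
      mzo[i] <- (1 - w) * vms$mzo[[ci]][j] + w * vms$mzo[[ci]][j + 1L]
    }
  }
  tr <- unlist(vms$traces_by_chem[act], use.names = FALSE)
  reps <- lengths(vms$traces_by_chem[act])
  mz <- vms$trace_mz[tr] + rep(mzo, reps)
  int <- vms$trace_prop[tr] * rep(rel * vms$chem_max[act], reps)
  keep <- int > 0
  list(trace = tr[keep], chem = rep(act, reps)[keep],
       mz = mz[keep], intensity = int[keep])
}

#' Execute one scan request on the virtual mass spectrometer
#'
#' Evaluates all eluting chemicals at the current clock RT, produces the
#' requested MS1 or MS2 scan, stamps it with the clock, then advances the
#' clock by a duration sampled from the feature database for the level
#' transition (previous scan level to this scan's level).
#'
#' @param vms A [virtual_ms()].
#' @param request A list with `ms_level`, and for level 2 `isolation`
#'   (`c(lo, hi)`), `precursor_mz`, and optionally `precursor_intensity`
#'   (recorded at selection time by DDA controllers) and `parent_scan`.
#' @return The completed `ms_scan` (also appended to the internal log).
#' @export
generate_scan <- function(vms, request) {
  level <- as.integer(request$ms_level)
  t <- vms$clock
  sig <- .eluting_traces(vms, t)
  id <- vms$n_scans + 1L

  if (level == 1L) {
    scan <- ms_scan(id, 1L, t, NA_real_, sig$mz, sig$intensity)
    vms$last_ms1_id <- id
  } else {
    iso <- request$isolation
    if (is.null(iso) || length(iso) != 2L || iso[1L] >= iso[2L])
      stop("an MS2 scan request needs an isolation window c(lo, hi)")
    sel <- which(sig$mz >= iso[1L] & sig$mz <= iso[2L])
    fmz <- numeric(0); fint <- numeric(0)
    for (s in sel) {
      fr <- vms$chemicals[[sig$chem[s]]]$fragments
      if (nrow(fr)) {
        fmz <- c(fmz, fr$mz)
        fint <- c(fint, fr$rel_intensity * sig$intensity[s])
      }
    }
    prec_int <- request$precursor_intensity
    if (is.null(prec_int) || is.na(prec_int)) {
      ## measure the precursor at execution time: the in-window trace
      ## closest in m/z to the requested precursor (strongest trace if no
      ## target m/z was given)
      prec_int <- if (!length(sel)) 0
      else if (!is.null(request$precursor_mz) &&
               !is.na(request$precursor_mz))
        sig$intensity[sel[which.min(abs(sig$mz[sel] -
                                        request$precursor_mz))]]
      else max(sig$intensity[sel])
    }
    scan <- ms_scan(id, 2L, t, NA_real_, fmz, fint,
                    precursor = list(
                      mz = request$precursor_mz,
                      intensity = prec_int,
                      scan_id = if (!is.null(request$parent_scan))
                        request$parent_scan else vms$last_ms1_id),
                    isolation = iso)
  }

  dur <- if (!is.null(vms$duration_fn))
    vms$duration_fn(vms$prev_level, level)
  else sample_scan_duration(vms$db, vms$prev_level, level)
  scan$duration <- dur

  if (id > length(vms$scans))
    vms$scans <- c(vms$scans, vector("list", length(vms$scans)))
  vms$scans[[id]] <- scan
  vms$n_scans <- id
  vms$clock <- t + dur
  vms$prev_level <- level
  scan
}

#' Generate a single MS1 or MS2 scan
#'
#' Convenience wrappers around [generate_scan()] mirroring the two request
#' types.
#'
#' @inheritParams generate_scan
#' @param isolation Isolation window `c(lo, hi)` for MS2.
#' @param precursor_mz Precursor m/z recorded in the MS2 scan metadata.
#' @param precursor_intensity Optional precursor intensity recorded at
#'   selection time; when missing, the most intense trace currently in the
#'   window is recorded.
#' @return The completed `ms_scan`.
#' @export
generate_ms1_scan <- function(vms)
  generate_scan(vms, list(ms_level = 1L))

#' @rdname generate_ms1_scan
#' @export
generate_ms2_scan <- function(vms, isolation, precursor_mz,
                              precursor_intensity = NULL)
  generate_scan(vms, list(ms_level = 2L, isolation = isolation,
                          precursor_mz = precursor_mz,
                          precursor_intensity = precursor_intensity))

#' Run an acquisition under a controller
#'
#' The acquisition loop: the controller supplies the next scan request,
#' the virtual mass spectrometer executes it at the current clock RT and
#' advances the clock by a sampled duration, and the completed scan is
#' broadcast back to the controller before the next request is taken. The
#' loop ends when the clock reaches `end_rt`. A controller returning no
#' request defaults to a full MS1 scan.
#'
#' @param chemicals List of chemical objects.
#' @param controller A controller (see [ms1_controller()],
#'   [top_n_controller()], [scheduled_controller()]).
#' @param db A `spectral_feature_db`.
#' @param start_rt,end_rt Acquisition window (s).
#' @param duration_fn Optional fixed-timing override, see [virtual_ms()].
#' @return A `scan_log`: list of `ms_scan` objects in acquisition order.
#' @export
run_acquisition <- function(chemicals, controller, db, start_rt, end_rt,
                            duration_fn = NULL) {
  vms <- virtual_ms(chemicals, db, start_rt, end_rt, duration_fn)
  if (!is.null(controller$start)) controller$start(start_rt, end_rt)
  while (vms$clock < end_rt) {
    req <- controller$next_request(vms$clock)
    if (is.null(req)) req <- list(ms_level = 1L)
    scan <- generate_scan(vms, req)
    if (!is.null(controller$scan_done)) controller$scan_done(scan)
  }
  if (!is.null(controller$end)) controller$end()
  structure(vms$scans[seq_len(vms$n_scans)], class = "scan_log")
}

#' @export
print.scan_log <- function(x, ...) {
  lv <- vapply(x, `[[`, 1L, "ms_level")
  cat(sprintf("Scan log: %d scans (%d MS1, %d MS2), RT %.1f-%.1f s\n",
              length(x), sum(lv == 1L), sum(lv == 2L),
              if (length(x)) x[[1L]]$rt else NA,
              if (length(x)) x[[length(x)]]$rt else NA))
  invisible(x)
}
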