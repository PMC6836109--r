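# Shared test helpers: tiny scan builders and independent brute-force
# oracles used to cross-check the package implementations.

make_scan <- function(rt, mz, intensity, level = 1L, id = 0L)
  ms_scan(id, level, rt, 0.1, mz, intensity)

# Independent brute-force ROI grouper. Implements the grouping rules with
# explicit nested loops and repeated global-best search: a point joins the
# open ROI with the closest mean m/z within the ppm window (ties: earlier
# ROI, then lower point m/z); one point per ROI per scan; leftover points
# seed new ROIs; ROIs not extended in a scan are closed.
oracle_group_rois <- function(scans, mz_tol_ppm, min_point_intensity,
                              min_points) {
  open <- list()
  closed <- list()
  created <- 0L
  for (s in scans) {
    if (!is.null(s$ms_level) && s$ms_level != 1L) next
    idx <- which(s$intensity >= min_point_intensity)
    pmz <- s$mz[idx]; pint <- s$intensity[idx]
    o <- order(pmz); pmz <- pmz[o]; pint <- pint[o]
    taken <- rep(FALSE, length(pmz))
    extended <- rep(FALSE, length(open))
    repeat {
      bp <- 0L; br <- 0L; bd <- Inf
      for (p in seq_along(pmz)) {
        if (taken[p]) next
        for (r in seq_along(open)) {
          if (extended[r]) next
          m <- mean(open[[r]]$mz)
          d <- abs(pmz[p] - m)
          if (d > m * mz_tol_ppm * 1e-6) next
          if (d < bd ||
              (d == bd && (open[[r]]$created < open[[br]]$created ||
                           (open[[r]]$created == open[[br]]$created &&
                            pmz[p] < pmz[bp])))) {
            bp <- p; br <- r; bd <- d
          }
        }
      }
      if (bp == 0L) break
      open[[br]]$mz <- c(open[[br]]$mz, pmz[bp])
      open[[br]]$rt <- c(open[[br]]$rt, s$rt)
      open[[br]]$intensity <- c(open[[br]]$intensity, pint[bp])
      taken[bp] <- TRUE; extended[br] <- TRUE
    }
    for (p in seq_along(pmz)) {
      if (taken[p]) next
      created <- created + 1L
      open[[length(open) + 1L]] <- list(mz = pmz[p], rt = s$rt,
                                        intensity = pint[p],
                                        created = created)
      extended <- c(extended, TRUE)
    }
    closed <- c(closed, open[!extended])
    open <- open[extended]
  }
  closed <- c(closed, open)
  closed <- Filter(function(r) length(r$mz) >= min_points, closed)
  lapply(closed, function(r) data.frame(mz = r$mz, rt = r$rt,
                                        intensity = r$intensity))
}

# canonical form for comparing ROI sets regardless of output order
roi_canonical <- function(rois) {
  keys <- vapply(rois, function(r)
    paste(sprintf("%.9f:%.4f:%.4f", r$mz, r$rt, r$intensity),
          collapse = "|"), "")
  sort(keys)
}

# Independent brute-force confusion counting straight from the class
# definitions, with nested loops over peaks and events.
oracle_confusion <- function(full, frag, events, min_intensity, ppm = 10) {
  hit <- function(pk) {
    for (j in seq_len(nrow(events))) {
      if (events$precursor_intensity[j] >= min_intensity &&
          events$precursor_mz[j] >= pk$mz_lo &&
          events$precursor_mz[j] <= pk$mz_hi &&
          events$rt[j] >= pk$rt_lo && events$rt[j] <= pk$rt_hi)
        return(TRUE)
    }
    FALSE
  }
  matched <- function(pk, other) {
    for (j in seq_len(nrow(other))) {
      if (abs(other$mz[j] - pk$mz) <= pk$mz * ppm * 1e-6 &&
          other$rt_lo[j] <= pk$rt_hi && other$rt_hi[j] >= pk$rt_lo)
        return(TRUE)
    }
    FALSE
  }
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(frag))) {
    pk <- frag[i, ]
    m <- matched(pk, full); h <- hit(pk)
    if (m && h) tp <- tp + 1L
    if (!m && h) fp <- fp + 1L
    if (!m && !h) tn <- tn + 1L
    if (m && !h) fn <- fn + 1L  # ground truth left unfragmented
  }
  for (i in seq_len(nrow(full))) {
    pk <- full[i, ]
    if (!matched(pk, frag) && !hit(pk)) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# random picked-peak toys for the confusion oracle comparison
random_peak_table <- function(n) {
  mz <- runif(n, 100, 500)
  rt <- runif(n, 0, 100)
  data.frame(mz = mz, mz_lo = mz - 0.05, mz_hi = mz + 0.05,
             rt_lo = rt, rt_hi = rt + runif(n, 2, 10),
             apex_rt = rt + 1,
             apex_intensity = 10^runif(n, 4, 7))
}
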