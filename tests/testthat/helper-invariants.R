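# Structural invariants of a DDA scan log, used by several test files.

scan_levels <- function(log) vapply(log, `[[`, 1L, "ms_level")

# (a) at most N fragmentation scans between consecutive survey scans
max_ms2_burst <- function(log) {
  lv <- scan_levels(log)
  r <- rle(lv)
  if (any(r$values == 2L)) max(r$lengths[r$values == 2L]) else 0L
}

# (b) smallest time gap between two fragmentations of the same precursor
# m/z (within mz_tol); Inf when no precursor is fragmented twice
min_refragmentation_gap <- function(log, mz_tol = 0.01) {
  ev <- fragmentation_events(log)
  gap <- Inf
  if (nrow(ev) < 2L) return(gap)
  for (i in seq_len(nrow(ev) - 1L)) {
    same <- which(abs(ev$precursor_mz[-seq_len(i)] - ev$precursor_mz[i])
                  <= mz_tol) + i
    if (length(same))
      gap <- min(gap, min(abs(ev$rt[same] - ev$rt[i])))
  }
  gap
}

# (c) every fragmented precursor was at or above the selection threshold
# in the survey scan that triggered it
survey_intensities <- function(log, mz_tol = 0.01) {
  by_id <- list()
  for (s in log) by_id[[as.character(s$scan_id)]] <- s
  out <- numeric(0)
  for (s in log) {
    if (s$ms_level != 2L || is.null(s$precursor)) next
    parent <- by_id[[as.character(s$precursor$scan_id)]]
    near <- which(abs(parent$mz - s$precursor$mz) <= mz_tol)
    out <- c(out, if (length(near)) max(parent$intensity[near]) else 0)
  }
  out
}
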