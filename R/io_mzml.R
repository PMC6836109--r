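#' Read a centroided mzML run
#'
#' Loads all spectra of an mzML file into the package's scan container,
#' ordered by retention time, preserving MS levels, centroid arrays (to
#' double precision), and MS2 precursor / isolation-window metadata.
#'
#' @param path Path to an mzML file.
#' @return A `scan_log`: list of [ms_scan()] objects.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hdr <- mzR::header(fh)
  pks <- mzR::peaks(fh)
  if (nrow(hdr) == 1L) pks <- list(pks)
  o <- order(hdr$retentionTime)

  scans <- vector("list", nrow(hdr))
  for (k in seq_along(o)) {
    i <- o[k]
    p <- pks[[i]]
    prec <- NULL; iso <- NULL
    if (hdr$msLevel[i] == 2L) {
      prec <- list(mz = hdr$precursorMZ[i],
                   intensity = hdr$precursorIntensity[i],
                   scan_id = hdr$precursorScanNum[i])
      tgt <- hdr$isolationWindowTargetMZ[i]
      if (!is.na(tgt))
        iso <- c(tgt - hdr$isolationWindowLowerOffset[i],
                 tgt + hdr$isolationWindowUpperOffset[i])
    }
    scans[[k]] <- ms_scan(k, hdr$msLevel[i], hdr$retentionTime[i],
                          duration = NA_real_,
                          mz = unname(p[, 1L]),
                          intensity = unname(p[, 2L]),
                          precursor = prec, isolation = iso)
  }
  ## scan duration observable only as the RT gap to the next scan
  for (k in seq_along(scans)) {
    if (k < length(scans))
      scans[[k]]$duration <- scans[[k + 1L]]$rt - scans[[k]]$rt
  }
  structure(scans, class = "scan_log")
}

#' Write a scan log as mzML
#'
#' Serializes a simulated (or loaded) run as standards-conformant indexed
#' mzML with zlib-compressed 64-bit arrays. All spectra are written as
#' centroided; MS2 scans carry precursor m/z, precursor intensity, and
#' the isolation window. Retention times are in seconds.
#'
#' @param scan_log A non-empty `scan_log`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mzml <- function(scan_log, path) {
  n <- length(scan_log)
  if (n == 0L) stop("refusing to write an empty scan log")
  pk <- lapply(scan_log, function(s)
    cbind(mz = as.numeric(s$mz), intensity = as.numeric(s$intensity)))
  g1 <- function(f) vapply(scan_log, f, 1.0)
  lv <- vapply(scan_log, function(s) s$ms_level, 1L)
  npk <- vapply(scan_log, function(s) length(s$mz), 1L)
  prec_mz <- g1(function(s)
    if (!is.null(s$precursor)) s$precursor$mz else NA_real_)
  prec_int <- g1(function(s)
    if (!is.null(s$precursor)) s$precursor$intensity else NA_real_)
  prec_scan <- vapply(scan_log, function(s)
    if (!is.null(s$precursor) && !is.null(s$precursor$scan_id))
      as.integer(s$precursor$scan_id) else NA_integer_, 1L)
  iso_lo <- g1(function(s)
    if (!is.null(s$isolation)) s$isolation[1L] else NA_real_)
  iso_hi <- g1(function(s)
    if (!is.null(s$isolation)) s$isolation[2L] else NA_real_)
  iso_tgt <- ifelse(lv == 2L & !is.na(prec_mz), prec_mz, NA_real_)
  ## default the window to the precursor when a request carried none
  iso_lo <- ifelse(lv == 2L & is.na(iso_lo), iso_tgt, iso_lo)
  iso_hi <- ifelse(lv == 2L & is.na(iso_hi), iso_tgt, iso_hi)

  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = lv, polarity = rep(1L, n), peaksCount = npk,
    totIonCurrent = g1(function(s) sum(s$intensity)),
    retentionTime = g1(function(s) s$rt),
    basePeakMZ = g1(function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0),
    basePeakIntensity = g1(function(s)
      if (length(s$intensity)) max(s$intensity) else 0),
    collisionEnergy = ifelse(lv == 2L, 25, NA_real_),
    ionisationEnergy = rep(0, n),
    lowMZ = g1(function(s) if (length(s$mz)) min(s$mz) else 0),
    highMZ = g1(function(s) if (length(s$mz)) max(s$mz) else 0),
    precursorScanNum = prec_scan, precursorMZ = prec_mz,
    precursorCharge = ifelse(lv == 2L, 1L, NA_integer_),
    precursorIntensity = prec_int,
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_,
    mergedResultEndScanNum = NA_integer_,
    injectionTime = rep(0, n), filterString = NA_character_,
    centroided = rep(TRUE, n), ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = iso_tgt,
    isolationWindowLowerOffset = iso_tgt - iso_lo,
    isolationWindowUpperOffset = iso_hi - iso_tgt,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    spectrumId = paste0("scan=", seq_len(n))
  )
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
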