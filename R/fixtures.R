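#' Generate a parametric spectral feature database
#'
#' Builds a database with the same structure as [build_feature_db()] but
#' from stated parametric distributions, so every downstream module can be
#' exercised without experimental input: MS1 feature m/z uniform in
#' 70-1000 Th, RT uniform over `rt_range`, log10 maximum intensity
#' uniform in 4-7; MS2 peak m/z uniform in 50-500 Th with log10 intensity
#' uniform in 2-5; per-scan fragment counts uniform over
#' `fragment_count_range`; scan durations normal around the supplied
#' transition means (truncated positive), or exactly the means when
#' `duration_sd_frac = 0`.
#'
#' @param n_ms1,n_ms2 Pool sizes (> 0).
#' @param duration_means Named list of mean scan durations (s) per level
#'   transition, e.g. `list("1->1" = 0.6, "1->2" = 0.2, ...)`.
#' @param n_durations Draws per transition pool.
#' @param duration_sd_frac Relative SD of the duration jitter.
#' @param rt_range RT window (s) for MS1 feature retention times.
#' @param mz_range,log10_intensity_range MS1 feature ranges.
#' @param fragment_count_range Integer range of per-scan fragment counts.
#' @param formulas Optional formula list to store (for the synthetic
#'   sample workflow); defaults to [fixture_formulas()].
#' @param chromatograms Optional list of `normalized_roi` templates;
#'   defaults to Gaussian templates of assorted widths.
#' @return A `spectral_feature_db`.
#' @export
make_fixture_db <- function(n_ms1 = 200, n_ms2 = 500,
                            duration_means = list("1->1" = 0.6,
                                                  "1->2" = 0.2,
                                                  "2->1" = 0.6,
                                                  "2->2" = 0.2),
                            n_durations = 50, duration_sd_frac = 0.05,
                            rt_range = c(0, 400),
                            mz_range = c(70, 1000),
                            log10_intensity_range = c(4, 7),
                            fragment_count_range = c(5L, 30L),
                            formulas = fixture_formulas(),
                            chromatograms = NULL) {
  stopifnot(n_ms1 > 0, n_ms2 > 0)
  ms1 <- data.frame(
    mz = stats::runif(n_ms1, mz_range[1], mz_range[2]),
    rt = stats::runif(n_ms1, rt_range[1], rt_range[2]),
    max_intensity = 10^stats::runif(n_ms1, log10_intensity_range[1],
                                    log10_intensity_range[2]))
  ms2 <- data.frame(
    mz = stats::runif(n_ms2, 50, 500),
    intensity = 10^stats::runif(n_ms2, 2, 5))
  frag_counts <- sample(fragment_count_range[1]:fragment_count_range[2],
                        100, replace = TRUE)
  durations <- lapply(duration_means, function(m) {
    d <- stats::rnorm(n_durations, m, duration_sd_frac * m)
    pmax(d, m * 0.2)
  })
  if (is.null(chromatograms))
    chromatograms <- lapply(stats::runif(20, 2, 8), function(sd)
      gaussian_chromatogram(sd_rt = sd,
                            apex_intensity = 10^stats::runif(1, 4, 7)))
  structure(list(ms1_features = ms1, ms2_peaks = ms2,
                 fragment_counts = as.integer(frag_counts),
                 scan_durations = durations,
                 chromatograms = chromatograms, formulas = formulas),
            class = "spectral_feature_db")
}

#' Gaussian chromatogram template
#'
#' A closed-form chromatographic shape for fixtures: a Gaussian in RT
#' (apex at `3 * sd_rt`, truncated at +/- 3 sd), sampled at `knot_step`
#' intervals, with zero m/z drift.
#'
#' @param sd_rt Peak width (Gaussian SD, s).
#' @param knot_step Knot spacing (s).
#' @param apex_intensity Apex intensity recorded in the template's
#'   `apex_intensity` attribute (used for intensity-similarity matching).
#' @return A `normalized_roi`.
#' @export
gaussian_chromatogram <- function(sd_rt = 5, knot_step = 1,
                                  apex_intensity = 1e6) {
  half <- 3 * sd_rt
  rt <- seq(0, 2 * half, by = knot_step)
  if (rt[length(rt)] < 2 * half) rt <- c(rt, 2 * half)
  rel <- exp(-(rt - half)^2 / (2 * sd_rt^2))
  rel <- rel / max(rel)
  structure(data.frame(mz_offset = rep(0, length(rt)), rt_offset = rt,
                       rel_intensity = rel),
            apex_intensity = apex_intensity,
            apex_rt_offset = half,
            class = c("normalized_roi", "data.frame"))
}

#' A small list of plausible metabolite-like molecular formulas
#'
#' CHNOPS formulas spanning roughly 70-900 Da, used as the default
#' formula pool of fixture databases.
#'
#' @param n Number of formulas (recycled from a base set with random
#'   CHNO increments when `n` exceeds the base set).
#' @return Character vector of formula strings.
#' @export
fixture_formulas <- function(n = 100) {
  base <- c("C3H7NO2", "C4H9NO3", "C5H9NO4", "C6H12O6", "C6H13NO2",
            "C9H11NO2", "C9H11NO3", "C11H12N2O2", "C10H13N5O4",
            "C10H12N4O5", "C5H5N5", "C4H6O5", "C6H8O7", "C3H4O3",
            "C7H6O2", "C10H16N2O3S", "C63H88CoN14O14P", "C27H46O",
            "C19H19N7O6", "C8H10NO6P", "C21H27N7O14P2", "C10H14N2O5",
            "C12H22O11", "C7H15NO3", "C5H11NO2S", "C6H14N4O2",
            "C4H7NO4", "C5H10N2O3", "C3H7NO3", "C5H7NO3")
  if (n <= length(base)) return(base[seq_len(n)])
  extra <- vapply(seq_len(n - length(base)), function(i) {
    c_n <- sample(4:30, 1); h_n <- sample(c_n:(2 * c_n + 2), 1)
    n_n <- sample(0:5, 1); o_n <- sample(1:10, 1)
    paste0("C", c_n, "H", h_n, if (n_n) paste0("N", n_n), "O", o_n)
  }, "")
  c(base, extra)
}

#' Generate fixture chemicals with known ground truth
#'
#' Creates unknown chemicals with Gaussian chromatograms, uniformly spaced
#' random m/z (70-1000 Th), apex RTs uniform inside `rt_range`, and log10
#' apex intensities uniform in `log10_intensity_range`, together with a
#' machine-readable ground-truth table of each chemical's true box.
#'
#' @param n Number of chemicals.
#' @param rt_range Window (s) containing every apex.
#' @param sd_rt_range Range of Gaussian peak widths (s).
#' @param mz_range,log10_intensity_range Sampling ranges.
#' @param db Optional `spectral_feature_db` used to assign fragment
#'   spectra via [assign_fragments()].
#' @param fragment_method,crp Passed to [assign_fragments()].
#' @return A list with `chemicals` (list of `unknown_chemical`) and
#'   `truth` (data frame `id`, `mz`, `mz_lo`, `mz_hi`, `rt_lo`, `rt_hi`,
#'   `apex_rt`, `apex_intensity`).
#' @export
make_fixture_chemicals <- function(n, rt_range = c(30, 270),
                                   sd_rt_range = c(3, 7),
                                   mz_range = c(70, 1000),
                                   log10_intensity_range = c(4, 7),
                                   db = NULL,
                                   fragment_method = "random",
                                   crp = NULL) {
  mz <- stats::runif(n, mz_range[1], mz_range[2])
  apex_rt <- stats::runif(n, rt_range[1], rt_range[2])
  sd_rt <- stats::runif(n, sd_rt_range[1], sd_rt_range[2])
  apex_int <- 10^stats::runif(n, log10_intensity_range[1],
                              log10_intensity_range[2])
  chems <- vector("list", n)
  for (i in seq_len(n)) {
    ch <- gaussian_chromatogram(sd_rt[i], apex_intensity = apex_int[i])
    frags <- if (!is.null(db))
      assign_fragments(db, method = fragment_method, crp = crp)
    else empty_fragments()
    chems[[i]] <- unknown_chemical(
      mz = mz[i], start_rt = apex_rt[i] - 3 * sd_rt[i],
      max_intensity = apex_int[i], chromatogram = ch,
      fragments = frags, id = i)
  }
  truth <- data.frame(id = seq_len(n), mz = mz,
                      mz_lo = mz - 0.01, mz_hi = mz + 0.01,
                      rt_lo = apex_rt - 3 * sd_rt,
                      rt_hi = apex_rt + 3 * sd_rt,
                      apex_rt = apex_rt, apex_intensity = apex_int)
  list(chemicals = chems, truth = truth)
}

#' Write a fixture full-scan run as mzML with ground truth
#'
#' Renders the supplied chemicals with the MS1 controller on a fixed scan
#' period, writes the run as mzML, and returns the ground-truth peak
#' table (also written as CSV next to the mzML when `truth_path` is
#' given).
#'
#' @param chemicals List of chemical objects (see
#'   [make_fixture_chemicals()]).
#' @param truth Ground-truth table matching `chemicals`.
#' @param path Output mzML path.
#' @param scan_period Fixed MS1 scan period (s).
#' @param rt_range Acquisition window (s).
#' @param truth_path Optional CSV path for the ground-truth table.
#' @return Invisibly, a list with `path` and `truth`.
#' @export
make_fixture_run <- function(chemicals, truth, path, scan_period = 0.6,
                             rt_range = c(0, 300), truth_path = NULL) {
  if (length(chemicals) && anyDuplicated(round(truth$mz, 2)))
    warning("fixture contains chemicals with near-identical m/z")
  db <- structure(list(ms1_features = data.frame(),
                       ms2_peaks = data.frame(),
                       fragment_counts = integer(0),
                       scan_durations = list("1->1" = scan_period),
                       chromatograms = list(), formulas = NULL),
                  class = "spectral_feature_db")
  log <- run_acquisition(chemicals, ms1_controller(), db,
                         rt_range[1], rt_range[2],
                         duration_fn = function(p, n) scan_period)
  if (length(log) == 0L) stop("fixture run produced no scans")
  write_mzml(log, path)
  if (!is.null(truth_path))
    utils::write.csv(truth, truth_path, row.names = FALSE)
  invisible(list(path = path, truth = truth))
}
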