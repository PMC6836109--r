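fixed_durations <- function(p, n) if (n == 1L) 0.6 else 0.2

one_chem <- function(mz = 200, start_rt = 10, max_int = 1e6,
                     fragments = empty_fragments())
  unknown_chemical(mz, start_rt, max_int,
                   gaussian_chromatogram(sd_rt = 5), fragments = fragments)

empty_db <- function()
  structure(list(ms1_features = data.frame(), ms2_peaks = data.frame(),
                 fragment_counts = integer(0),
                 scan_durations = list("1->1" = 0.6),
                 chromatograms = list(), formulas = NULL),
            class = "spectral_feature_db")

test_that("scans sort their centroids by m/z", {
  s <- ms_scan(1, 1, 0, 0.1, c(300, 100, 200), c(3, 1, 2))
  expect_equal(s$mz, c(100, 200, 300))
  expect_equal(s$intensity, c(1, 2, 3))
})

test_that("chromatogram interpolation is linear, exact at knots, zero outside", {
  ch <- structure(data.frame(mz_offset = c(0, 0.01), rt_offset = c(0, 1),
                             rel_intensity = c(0.2, 0.8)),
                  apex_intensity = 100, apex_rt_offset = 1,
                  class = c("normalized_roi", "data.frame"))
  expect_equal(interpolate_signal(ch, 0.25),
               c(rel_intensity = 0.35, mz_offset = 0.0025))
  expect_equal(interpolate_signal(ch, 0),
               c(rel_intensity = 0.2, mz_offset = 0))
  expect_equal(interpolate_signal(ch, 1),
               c(rel_intensity = 0.8, mz_offset = 0.01))
  expect_equal(interpolate_signal(ch, -0.1),
               c(rel_intensity = 0, mz_offset = 0))
  expect_equal(interpolate_signal(ch, 1.5),
               c(rel_intensity = 0, mz_offset = 0))
})

test_that("an MS1 scan at the apex reports the chemical at full intensity", {
  ch <- one_chem()
  vms <- virtual_ms(list(ch), empty_db(), start_rt = 25, end_rt = 50,
                    duration_fn = fixed_durations)
  s <- generate_ms1_scan(vms)
  expect_equal(s$ms_level, 1L)
  expect_equal(s$rt, 25)          # apex: start 10 + 3 * sd 5
  expect_equal(s$mz, 200)
  expect_equal(s$intensity, 1e6)
  expect_equal(vms$clock, 25.6)   # clock advanced by the MS1 duration
})

test_that("MS2 scans isolate by window, scale fragments and measure the precursor", {
  fr <- data.frame(mz = c(50, 60), rel_intensity = c(0.5, 1))
  ch <- one_chem(fragments = fr)
  vms <- virtual_ms(list(ch), empty_db(), 25, 50,
                    duration_fn = fixed_durations)
  s <- generate_ms2_scan(vms, isolation = c(199.5, 200.5),
                         precursor_mz = 200)
  expect_equal(s$ms_level, 2L)
  expect_equal(s$mz, c(50, 60))
  expect_equal(s$intensity, c(0.5e6, 1e6))
  expect_equal(s$precursor$intensity, 1e6)  # measured at execution time
  expect_equal(s$duration, 0.2)

  # empty window: no fragments, zero precursor intensity
  s2 <- generate_ms2_scan(vms, isolation = c(400, 401), precursor_mz = 400.5)
  expect_length(s2$mz, 0L)
  expect_equal(s2$precursor$intensity, 0)

  # a supplied selection-time intensity is recorded verbatim
  s3 <- generate_ms2_scan(vms, isolation = c(199.5, 200.5),
                          precursor_mz = 200, precursor_intensity = 123)
  expect_equal(s3$precursor$intensity, 123)

  expect_error(generate_scan(vms, list(ms_level = 2L)), "isolation")
})

test_that("signal decays away from the apex following the template", {
  ch <- one_chem()
  vms <- virtual_ms(list(ch), empty_db(), 20, 50,
                    duration_fn = fixed_durations)
  s <- generate_ms1_scan(vms)  # rt 20 = apex - 5 s = one sd early
  expect_equal(s$intensity, 1e6 * exp(-0.5), tolerance = 1e-9)
})

test_that("a full acquisition covers the window with increasing RTs", {
  set.seed(21)
  db <- make_fixture_db()
  chems <- sample_known_chemicals(db, 10)
  log <- run_acquisition(chems, ms1_controller(), db, 0, 60,
                         duration_fn = fixed_durations)
  expect_s3_class(log, "scan_log")
  expect_equal(length(log), 100L)  # 60 s at 0.6 s per MS1 scan
  rts <- vapply(log, `[[`, 1.0, "rt")
  expect_true(all(diff(rts) > 0))
  expect_true(all(scan_levels(log) == 1L))
  expect_true(max(rts) < 60)
  ids <- vapply(log, `[[`, 1L, "scan_id")
  expect_identical(ids, seq_along(log))
})

test_that("acquisitions are reproducible under a fixed seed", {
  set.seed(33)
  db <- make_fixture_db()
  chems <- sample_known_chemicals(db, 20, fragment_method = "random")
  run_once <- function() {
    set.seed(17)
    run_acquisition(chems, top_n_controller(top_n_params(N = 3)),
                    db, 0, 40)
  }
  a <- run_once(); b <- run_once()
  expect_equal(a, b)
})
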