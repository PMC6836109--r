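box <- function(mz, rt_lo = 10, rt_hi = 20)
  data.frame(mz = mz, mz_lo = mz - 0.05, mz_hi = mz + 0.05,
             rt_lo = rt_lo, rt_hi = rt_hi, apex_rt = (rt_lo + rt_hi) / 2,
             apex_intensity = 1e6)

test_that("event matching uses closed intervals on both axes", {
  pk <- box(100)
  on_edge <- data.frame(precursor_mz = c(99.95, 100.05, 100, 100),
                        rt = c(15, 15, 10, 20),
                        precursor_intensity = 1e6)
  for (i in 1:4)
    expect_true(match_events(on_edge[i, ], pk, 1e5))
  outside <- data.frame(precursor_mz = c(99.94, 100, 100),
                        rt = c(15, 9.99, 20.01),
                        precursor_intensity = 1e6)
  for (i in 1:3)
    expect_false(match_events(outside[i, ], pk, 1e5))
  weak <- data.frame(precursor_mz = 100, rt = 15,
                     precursor_intensity = 1e4)
  expect_false(match_events(weak, pk, 1e5))
  expect_length(match_events(weak, pk[0, ], 1e5), 0L)
})

test_that("confusion counting matches the worked four-class example", {
  full <- rbind(box(100), box(200), box(300))
  frag <- rbind(box(100), box(300), box(400))
  events <- data.frame(precursor_mz = c(100, 400), rt = 15,
                       precursor_intensity = 1e6)
  cc <- confusion_counts(full, frag, events, min_intensity = 1e5)
  # 100: in both files and fragmented (TP); 400: frag-only, fragmented
  # (FP); 300: in both files but never fragmented (FN); 200: full-scan
  # only, unfragmented (FN)
  expect_equal(cc$tp, 1L)
  expect_equal(cc$fp, 1L)
  expect_equal(cc$fn, 2L)
  expect_equal(cc$tn, 0L)
  expect_equal(cc$precision, 0.5)
  expect_equal(cc$recall, 1 / 3)
  expect_equal(cc$f1, 0.4)
  expect_warning(confusion_counts(full[0, ], frag, events), "ground truth")
})

test_that("degenerate ratios are reported as zero and flagged", {
  r <- prf1(list(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_equal(c(r$precision, r$recall, r$f1), c(0, 0, 0))
  expect_setequal(r$undefined, c("precision", "recall", "f1"))
  r2 <- prf1(list(tp = 3, fp = 1, fn = 0))
  expect_equal(r2$precision, 0.75)
  expect_equal(r2$recall, 1)
  expect_length(r2$undefined, 0L)
})

test_that("confusion counting agrees with the brute-force oracle on random toys", {
  set.seed(77)
  for (rep in 1:50) {
    full <- random_peak_table(sample(1:8, 1))
    frag <- random_peak_table(sample(1:8, 1))
    # force some cross-file matches and some event hits
    if (nrow(full) > 1 && nrow(frag) > 1) frag[1, ] <- full[1, ]
    events <- data.frame(
      precursor_mz = c(frag$mz[1], runif(3, 100, 500)),
      rt = c(frag$rt_lo[1], runif(3, 0, 100)),
      precursor_intensity = 10^runif(4, 4, 7))
    cc <- confusion_counts(full, frag, events, min_intensity = 1e5)
    want <- oracle_confusion(full, frag, events, 1e5)
    expect_equal(list(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn),
                 want)
  }
})

test_that("the naive picker boxes each chromatographic peak", {
  ch <- unknown_chemical(200, 10, 1e6, gaussian_chromatogram(5))
  db <- make_fixture_db(n_ms1 = 5, n_ms2 = 5)
  log <- run_acquisition(list(ch), ms1_controller(), db, 0, 60,
                         duration_fn = function(p, n) 0.5)
  pk <- pick_peaks(log, min_intensity = 1e5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$mz, 200)
  expect_equal(pk$apex_intensity, 1e6, tolerance = 1e-3)
  expect_equal(pk$apex_rt, 25, tolerance = 0.5)   # apex at start + 3 sd
  expect_true(pk$rt_lo <= 11 && pk$rt_hi >= 39)
  expect_true(pk$mz_lo <= 199.99 && pk$mz_hi >= 200.01)
  # a threshold above the apex removes the peak
  expect_equal(nrow(pick_peaks(log, min_intensity = 2e6)), 0L)
})

test_that("grid evaluation returns one scored row per cell", {
  set.seed(55)
  db <- make_fixture_db()
  chems <- sample_known_chemicals(db, 30)
  chems <- lapply(chems, function(ch) { ch$start_rt <- ch$start_rt %% 30; ch })
  res <- grid_evaluate(chems, db, n_values = c(2, 5), dew_values = 15,
                       start_rt = 0, end_rt = 60,
                       duration_fn = function(p, n) if (n == 1) 0.6 else 0.2)
  expect_equal(nrow(res), 2L)
  expect_equal(res$N, c(2, 5))
  expect_true(all(res$f1 >= 0 & res$f1 <= 1))
  expect_true(all(res$tp + res$fp + res$fn + res$tn > 0))
  expect_true(all(res$n_ms1_scans > 0))
})

test_that("picked peaks survive a CSV round trip", {
  pk <- box(123.456)
  path <- tempfile(fileext = ".csv")
  write_picked_peaks_csv(pk, path)
  back <- read_picked_peaks_csv(path)
  expect_equal(back$mz_lo, pk$mz_lo)
  expect_equal(back$apex_intensity, pk$apex_intensity)
  unlink(path)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_picked_peaks_csv(bad), "lacks column")
  unlink(bad)
})
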