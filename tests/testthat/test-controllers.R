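test_that("precursor selection orders by intensity and applies every filter", {
  p <- top_n_params(N = 2, min_ms1_intensity = 1.75e5)
  peaks <- data.frame(mz = c(100, 200, 300),
                      intensity = c(5e5, 9e5, 1e5))
  sel <- select_top_n(peaks, p)
  expect_equal(sel$mz, c(200, 100))          # 300 is below threshold

  # active exclusion removes the top peak; nothing else qualifies
  ex <- data.frame(mz = 200, expiry_rt = 50)
  expect_equal(select_top_n(peaks, p, ex, rt = 10)$mz, 100)
  # expired exclusion is ignored
  expect_equal(select_top_n(peaks, p, ex, rt = 60)$mz, c(200, 100))

  # near-identical m/z cannot both be picked in one cycle
  twins <- data.frame(mz = c(100.000, 100.005),
                      intensity = c(9e5, 8e5))
  expect_equal(select_top_n(twins, top_n_params(N = 5))$mz, 100.000)

  # intensity ties break towards lower m/z
  tie <- data.frame(mz = c(500, 400), intensity = c(7e5, 7e5))
  expect_equal(select_top_n(tie, p)$mz, c(400, 500))

  expect_equal(nrow(select_top_n(peaks, top_n_params(N = 0))), 0L)
})

test_that("the DDA controller queues N fragmentations then returns to survey scans", {
  ctl <- top_n_controller(top_n_params(N = 2, dew = 15))
  ms1 <- ms_scan(1L, 1L, 10, 0.6, c(100, 200, 300), c(5e5, 9e5, 2e5))
  ctl$scan_done(ms1)
  r1 <- ctl$next_request(10.6)
  r2 <- ctl$next_request(10.8)
  r3 <- ctl$next_request(11.0)
  expect_equal(r1$ms_level, 2L)
  expect_equal(r1$precursor_mz, 200)
  expect_equal(r1$isolation, c(199.5, 200.5))
  expect_equal(r1$parent_scan, 1L)
  expect_equal(r2$precursor_mz, 100)
  expect_equal(r3$ms_level, 1L)              # queue exhausted

  # fragmenting 200 excludes it at the next survey scan within the DEW
  ctl$scan_done(ms_scan(2L, 2L, 10.6, 0.2, numeric(0), numeric(0),
                        precursor = list(mz = 200, intensity = 9e5,
                                         scan_id = 1L),
                        isolation = c(199.5, 200.5)))
  ms1b <- ms_scan(3L, 1L, 12, 0.6, c(100, 200, 300), c(5e5, 9e5, 2e5))
  ctl$scan_done(ms1b)
  nxt <- ctl$next_request(12.6)
  expect_equal(nxt$precursor_mz, 100)
  expect_equal(ctl$next_request(12.8)$precursor_mz, 300)

  # after the window has elapsed the precursor is eligible again
  ms1c <- ms_scan(4L, 1L, 26, 0.6, c(200), c(9e5))
  ctl$scan_done(ms1c)
  expect_equal(ctl$next_request(26.6)$precursor_mz, 200)
})

test_that("a scheduled controller replays its plan then falls back to MS1", {
  reqs <- list(list(ms_level = 1L),
               list(ms_level = 2L, precursor_mz = 150,
                    isolation = c(149.5, 150.5)))
  ctl <- scheduled_controller(reqs)
  expect_equal(ctl$next_request(0)$ms_level, 1L)
  expect_equal(ctl$next_request(1)$precursor_mz, 150)
  expect_equal(ctl$next_request(2)$ms_level, 1L)
})

test_that("priority weighting favours intense unfragmented features", {
  expect_equal(dsda_priority(c(1e6, 1e6, 2e5), c(0, 1, 0.5)),
               c(1e6, 0, 1e5))
  expect_error(dsda_priority(1e5, 1.2))
  expect_error(dsda_priority(-1, 0))
})

test_that("multi-sample acquisition schedules MS2 slots on registry features", {
  set.seed(41)
  db <- make_fixture_db()
  base <- sample_known_chemicals(db, 60)
  base <- lapply(base, function(ch) { ch$start_rt <- ch$start_rt %% 40; ch })
  samples <- replicate_samples(base, 3)
  res <- dsda_run(samples, db, top_n_params(N = 4), start_rt = 0,
                  end_rt = 80)
  expect_length(res$scan_logs, 3L)
  expect_true(nrow(res$registry) > 0)
  expect_true(all(c("quality", "weight") %in% names(res$registry)))
  expect_true(all(res$registry$quality >= 0 & res$registry$quality <= 1))
  expect_equal(res$registry$weight,
               dsda_priority(res$registry$apex_intensity,
                             res$registry$quality))
  # later samples run a planned schedule: their MS2 targets come from the
  # registry built on earlier samples
  ev2 <- fragmentation_events(res$scan_logs[[2]])
  if (nrow(ev2))
    expect_true(all(vapply(ev2$precursor_mz, function(m)
      any(abs(res$registry$mz - m) < 1e-9), TRUE)))
})
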