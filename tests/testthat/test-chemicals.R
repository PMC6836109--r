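test_that("formula parsing and monoisotopic masses match reference values", {
  expect_equal(unname(parse_formula("C6H12O6")[c("C", "H", "O")]),
               c(6L, 12L, 6L))
  expect_equal(monoisotopic_mass("H2O"), 18.0105646, tolerance = 1e-3)
  expect_equal(monoisotopic_mass("C6H12O6"), 180.0633881, tolerance = 1e-3)
  expect_equal(adduct_mz(monoisotopic_mass("C6H12O6"),
                         default_adducts()[1, ]),
               181.0706646, tolerance = 1e-3)
  expect_error(parse_formula("C6?H12"), "cannot parse")
  expect_error(monoisotopic_mass("Xx2"), "unknown element")
})

test_that("isotope and adduct proportions are normalized", {
  iso <- isotope_proportions("C6H12O6")
  expect_length(iso, 3L)
  expect_equal(sum(iso), 1)
  expect_true(iso[1] > iso[2] && iso[2] > iso[3])
  ad <- default_adducts(c("M+H" = 3, "M+Na" = 1))
  expect_equal(sum(ad$proportion), 1)
  expect_equal(ad$proportion, c(0.75, 0.25))
  expect_error(default_adducts(c(Bogus = 1)))
})

test_that("chemical traces cover adduct x isotope with proportions summing to 1", {
  ch <- known_chemical("C6H12O6", start_rt = 10, max_intensity = 1e6,
                       chromatogram = gaussian_chromatogram(5),
                       adducts = default_adducts(c("M+H" = 0.8,
                                                   "M+Na" = 0.2)))
  tr <- chemical_traces(ch)
  expect_equal(nrow(tr), 2L * 3L)
  expect_equal(sum(tr$proportion), 1)
  # isotope spacing ~1.003 Th at charge 1
  mh <- sort(tr$base_mz)[1:3]
  expect_equal(diff(mh), rep(1.00286864, 2), tolerance = 1e-6)
  expect_equal(min(tr$base_mz), 181.0706646, tolerance = 1e-3)

  u <- unknown_chemical(250.1, 5, 1e5, gaussian_chromatogram(4))
  tu <- chemical_traces(u)
  expect_equal(tu$base_mz, 250.1)
  expect_equal(tu$proportion, 1)
})

test_that("ROIs convert to unknown chemicals preserving apex and start", {
  r <- structure(data.frame(mz = c(200.0, 200.0002, 200.0001),
                            rt = c(30, 31, 32),
                            intensity = c(1e4, 5e4, 2e4)),
                 class = c("roi", "data.frame"))
  ch <- chemicals_from_rois(list(r))[[1]]
  expect_s3_class(ch, "unknown_chemical")
  expect_equal(ch$mz, mean(r$mz))
  expect_equal(ch$start_rt, 30)
  expect_equal(ch$max_intensity, 5e4)
  expect_equal(nrow(ch$fragments), 0L)
})

test_that("synthetic chemicals are drawn from the database pools, reproducibly", {
  set.seed(5)
  db <- make_fixture_db()
  set.seed(9)
  chems <- sample_known_chemicals(db, 25)
  expect_length(chems, 25L)
  expect_identical(vapply(chems, `[[`, 1L, "id"), 1:25)
  expect_true(all(vapply(chems, function(c)
    c$max_intensity %in% db$ms1_features$max_intensity, TRUE)))
  expect_true(all(vapply(chems, function(c) nrow(c$fragments) > 0, TRUE)))
  expect_true(all(vapply(chems, function(c)
    max(c$fragments$rel_intensity) == 1, TRUE)))
  set.seed(9)
  again <- sample_known_chemicals(db, 25)
  expect_equal(chems, again)
  expect_identical(sample_known_chemicals(db, 0), list())
})

test_that("replicate generation keeps ids, floors intensities and respects dropout 0", {
  set.seed(3)
  db <- make_fixture_db()
  base <- sample_known_chemicals(db, 40)
  exact <- replicate_samples(base, 2)          # no noise, no dropout
  expect_equal(exact[[1]], base)
  expect_equal(exact[[2]], base)

  noisy <- replicate_samples(base, 3, noise_sd = 1e12)  # extreme noise
  for (s in noisy)
    expect_true(all(vapply(s, `[[`, 1.0, "max_intensity") >= 1))

  dropped <- replicate_samples(base, 2, dropout_prob = 0.5)
  ids <- lapply(dropped, function(s) vapply(s, `[[`, 1L, "id"))
  for (v in ids) expect_true(all(v %in% 1:40) && !anyDuplicated(v))
  expect_error(replicate_samples(base, 2, dropout_prob = 1), "< 1")
})

test_that("fragment spectra never contain a duplicate peak and CRP counts accumulate", {
  set.seed(13)
  db <- make_fixture_db()
  crp <- crp_state(concentration = 1)
  total <- 0L
  for (i in 1:50) {
    fr <- assign_fragments(db, method = "crp", crp = crp)
    expect_false(anyDuplicated(fr$mz) > 0)
    expect_equal(max(fr$rel_intensity), 1)
    total <- total + nrow(fr)
  }
  expect_equal(sum(crp$counts), total)  # one count increment per draw
  expect_error(assign_fragments(db, method = "crp"), "crp_state")

  rnd <- assign_fragments(db, method = "random", n_peaks = 12L)
  expect_equal(nrow(rnd), 12L)
  expect_equal(nrow(assign_fragments(db, n_peaks = 0L)), 0L)
})
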