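test_that("cohort design reproduces the six-stage sampling plan", {
  d <- make_cohort(40, 0, 74, seed = 1)
  expect_equal(nrow(d$donors), 40)
  expect_equal(as.integer(table(d$donors$age_stage)),
               c(8L, 2L, 3L, 5L, 17L, 5L))
  expect_true(all(d$donors$age >= 0 & d$donors$age <= 74))

  d6 <- make_cohort(6, 0, 74, seed = 1)
  expect_equal(as.integer(table(d6$donors$age_stage)), rep(1L, 6))

  d12 <- make_cohort(12, 0, 74, seed = 3)
  expect_true(all(table(d12$donors$age_stage) >= 1))

  expect_identical(make_cohort(20, 0, 74, seed = 7),
                   make_cohort(20, 0, 74, seed = 7))
  expect_error(make_cohort(0), "n_donors")
  expect_error(make_cohort(10, 50, 40), "age_min")
})

test_that("age responses are bounded logistics with the right asymptotes", {
  r <- age_response("increasing", floor = 0.8, ceiling = 1.3,
                    midpoint = 18, steepness = 0.12)
  expect_equal(age_amplitude(1e6, r), 1.3)
  expect_equal(age_amplitude(18, r), (0.8 + 1.3) / 2)
  ages <- seq(0, 74, by = 0.5)
  v <- age_amplitude(ages, r)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0.8 & v <= 1.3))

  rd <- age_response("decreasing", floor = 0.7, ceiling = 1.2,
                     midpoint = 20, steepness = 0.1)
  expect_true(all(diff(age_amplitude(ages, rd)) < 0))
})

test_that("noiseless mineral/matrix area ratio rises monotonically with age", {
  # oracle: numeric trapezoid integration of the generated noiseless spectra
  ages <- seq(0, 70, by = 10)
  ratio <- vapply(ages, function(a) {
    s <- generate_spectrum(test_entry(a), "ftir",
                           noise = zero_noise_model("ftir"), seed = 1)
    band_area(s, c(900, 1200)) / band_area(s, c(1592, 1712))
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
})

test_that("generate_spectrum builds the band model it claims", {
  # single pure-Gaussian band, no noise: peak value equals its amplitude
  bands <- band_spec("solo", 1000, 15, "mineral", 2.5, mix = 0,
                     response = "flat")
  s <- generate_spectrum(test_entry(30), "raman", bands = bands,
                         noise = zero_noise_model("raman"), seed = 1)
  expect_equal(band_intensity(s, 1000), 2.5, tolerance = 1e-9)

  # age contrast: mineral window grows relative to amide I
  s1 <- generate_spectrum(test_entry(1), "ftir",
                          noise = zero_noise_model("ftir"), seed = 1)
  s70 <- generate_spectrum(test_entry(70), "ftir",
                           noise = zero_noise_model("ftir"), seed = 1)
  r1 <- band_area(s1, c(900, 1200)) / band_area(s1, c(1592, 1712))
  r70 <- band_area(s70, c(900, 1200)) / band_area(s70, c(1592, 1712))
  expect_gt(r70, r1)

  # spike rate 0: no sample strays more than 6 sd from the smooth model
  nm <- noise_model("raman", spike_rate = 0, fluorescence_amplitude = 0,
                    replicate_jitter_sdlog = 0, replicate_band_sdlog = 0)
  s <- generate_spectrum(test_entry(30), "raman", noise = nm, seed = 5)
  clean <- generate_spectrum(test_entry(30), "raman",
                             noise = zero_noise_model("raman"), seed = 5)
  expect_true(all(abs(s$intensity - clean$intensity) < 6 * nm$additive_sd))

  # band centered off-axis is rejected at configuration time
  bad <- band_spec("off", 2500, 10, "mineral", 1)
  expect_error(generate_spectrum(test_entry(30), "raman", bands = bad),
               "outside the axis")
})

test_that("generated spectra and images are bit-identical under a seed", {
  a <- generate_spectrum(test_entry(42), "raman", seed = 123)
  b <- generate_spectrum(test_entry(42), "raman", seed = 123)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_spectrum(test_entry(42), "raman", seed = 124)))

  ia <- generate_ftir_image(test_entry(42), seed = 9, n_pixels = 64)
  ib <- generate_ftir_image(test_entry(42), seed = 9, n_pixels = 64)
  expect_identical(ia, ib)
})

test_that("FPA images have 1024 pixels and expose planted bad-pixel truth", {
  img <- generate_ftir_image(test_entry(25), seed = 2)
  expect_equal(ncol(img$intensities), 1024)
  expect_equal(length(img$wavenumber), length(ftir_axis()))

  # zero bad-pixel fraction: every pixel passes the quality chain
  clean_img <- generate_ftir_image(
    test_entry(25), noise = noise_model("ftir", bad_pixel_fraction = 0),
    seed = 2)
  corrected <- clean_img
  corrected$intensities <- osteospectra:::baseline_correct_matrix(
    clean_img$wavenumber, clean_img$intensities, 2)
  qf <- quality_filter(corrected)
  expect_equal(qf$report$n_kept, 1024)

  # planted truth is consistent with the truth attribute
  tr <- attr(img, "truth")
  expect_setequal(img$bad_pixels, c(tr$dead_pixels, tr$hot_pixels))
})

test_that("closed-form set-points agree with measured noiseless outcomes", {
  for (mod in c("ftir", "raman")) {
    for (a in c(5, 40)) {
      s <- generate_spectrum(test_entry(a), mod,
                             noise = zero_noise_model(mod), seed = 1)
      m <- compute_outcomes(s)
      sp <- expected_outcomes(a, mod)
      expect_equal(m$mineral_matrix, sp$mineral_matrix, tolerance = 0.02)
      expect_equal(m$carbonate_phosphate, sp$carbonate_phosphate,
                   tolerance = 0.02)
      expect_equal(m$crystallinity, sp$crystallinity, tolerance = 0.02)
      expect_equal(m$collagen_maturity, sp$collagen_maturity,
                   tolerance = 0.02)
    }
  }
})
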