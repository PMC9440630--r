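test_that("band areas match analytic integrals", {
  # unit-height rectangle of width 100
  x <- seq(300, 2000, by = 1)
  y <- as.numeric(x >= 950 & x <= 1050)
  s <- spectrum(x, y, "raman")
  expect_equal(band_area(s, c(950, 1050)), 100, tolerance = 0.02)

  # Gaussian fully inside the window: A sigma sqrt(2 pi)
  g <- gaussian_spectrum(center = 1000, sigma = 12, amp = 3)
  expect_equal(band_area(g, c(900, 1100)), 3 * 12 * sqrt(2 * pi),
               tolerance = 0.01)

  expect_equal(band_area(g, c(1700, 1900)), 0, tolerance = 1e-6)
  expect_error(band_area(g, c(100, 200)), "outside")
})

test_that("band intensity interpolates linearly between channels", {
  s <- spectrum(c(1000, 1010, 1020), c(1, 3, 5), "raman")
  expect_equal(band_intensity(s, 1010), 3)
  expect_equal(band_intensity(s, 1005), 2)
  g <- gaussian_spectrum(center = 1030, sigma = 10)
  expect_equal(band_intensity(g, 1030) / band_intensity(g, 1020),
               exp(100 / 200), tolerance = 1e-4)
  expect_error(band_intensity(s, 999), "extrapolation")
})

test_that("FWHM matches the analytic widths of known profiles", {
  g <- gaussian_spectrum(center = 955, sigma = 5)
  expect_equal(fwhm(g, c(930, 980)), 2 * sqrt(2 * log(2)) * 5,
               tolerance = 0.01)
  l <- lorentzian_spectrum(center = 955, gamma = 8)
  expect_equal(fwhm(l, c(930, 980)), 16, tolerance = 0.01)
  # doubling sigma halves 1/FWHM
  g2 <- gaussian_spectrum(center = 955, sigma = 10)
  expect_equal(fwhm(g2, c(930, 980)) / fwhm(g, c(930, 980)), 2,
               tolerance = 0.01)
  flat <- spectrum(seq(930, 980), seq(1, 2, length.out = 51), "raman")
  expect_error(fwhm(flat, c(930, 980)), "local maximum")
})

test_that("FWHM agrees with dense-grid root finding on composite peaks", {
  # oracle: 0.001-resolution profile evaluation and direct crossing search
  bands <- default_band_table("raman")
  amps <- osteospectra:::band_amplitudes_at_age(bands, 40)
  grid <- seq(830, 1080, by = 0.001)   # same flank region as fwhm()
  prof <- drop(band_profiles(grid, bands) %*% amps)
  pk <- which.max(prof)
  half <- min(prof) + (prof[pk] - min(prof)) / 2
  left <- grid[max(which(prof[1:pk] < half))]
  right <- grid[pk + min(which(prof[-(1:pk)] < half)) - 1]
  oracle <- right - left

  s <- generate_spectrum(test_entry(40), "raman",
                         noise = zero_noise_model("raman"), seed = 1)
  expect_equal(fwhm(s, c(930, 980)), oracle, tolerance = 0.005)
})

test_that("every outcome is invariant to positive rescaling", {
  for (mod in c("ftir", "raman")) {
    s <- generate_spectrum(test_entry(33), mod,
                           noise = zero_noise_model(mod), seed = 8)
    for (c_scale in c(0.2, 7)) {
      s2 <- s
      s2$intensity <- s$intensity * c_scale
      a <- compute_outcomes(s)[, 5:8]
      b <- compute_outcomes(s2)[, 5:8]
      expect_equal(unlist(a), unlist(b), tolerance = 1e-12)
    }
  }
})

test_that("mineral-linked outcomes rise strictly across a noiseless age sweep", {
  ages <- seq(0, 70, by = 10)
  for (mod in c("ftir", "raman")) {
    panels <- do.call(rbind, lapply(ages, function(a) {
      s <- generate_spectrum(test_entry(a), mod,
                             noise = zero_noise_model(mod), seed = 1)
      compute_outcomes(s)
    }))
    for (v in c("mineral_matrix", "carbonate_phosphate", "crystallinity")) {
      expect_equal(cor(ages, panels[[v]], method = "spearman"), 1,
                   info = paste(mod, v))
    }
    # age 70 beats age 1 on all three mineral-linked outcomes
    p1 <- compute_outcomes(generate_spectrum(test_entry(1), mod,
                           noise = zero_noise_model(mod), seed = 1))
    p70 <- compute_outcomes(generate_spectrum(test_entry(70), mod,
                            noise = zero_noise_model(mod), seed = 1))
    expect_true(all(unlist(p70[, 5:7]) > unlist(p1[, 5:7])))
  }
})

test_that("band report covers the primary assignment windows", {
  s <- generate_spectrum(test_entry(30), "ftir",
                         noise = zero_noise_model("ftir"), seed = 1)
  br <- band_report(s)
  expect_true(all(c("po4_v1v3", "amide_ii", "amide_i", "co3_v2") %in% br$band))
  expect_true(all(br$area > 0))
})

test_that("outcome errors carry the outcome name", {
  s <- spectrum(seq(900, 1100, 4), rnorm(51), "ftir")
  expect_error(compute_outcomes(s), "mineral_matrix")
})

test_that("cohort outcome tables are tidy and complete", {
  d <- make_cohort(6, 0, 74, seed = 9)
  avgs <- cohort_raman_averages(d, seed = 9)
  tab <- cohort_outcomes(avgs)
  expect_equal(nrow(tab), 18)
  expect_true(all(unlist(tab[, c("mineral_matrix", "carbonate_phosphate",
                                 "crystallinity", "collagen_maturity")]) > 0))
  long <- outcomes_long(tab)
  expect_equal(nrow(long), 18 * 4)
  expect_setequal(unique(long$outcome),
                  c("mineral_matrix", "carbonate_phosphate",
                    "crystallinity", "collagen_maturity"))
})
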