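# Shared fixtures, all generated in code.

# Single analytic peak on a fine axis (oracle-friendly).
gaussian_spectrum <- function(center = 1000, sigma = 20, amp = 1,
                              axis = seq(300, 2000, by = 1), offset = 0,
                              modality = "raman") {
  spectrum(axis, amp * exp(-(axis - center)^2 / (2 * sigma^2)) + offset,
           modality = modality)
}

lorentzian_spectrum <- function(center = 1000, gamma = 20, amp = 1,
                                axis = seq(300, 2000, by = 1)) {
  spectrum(axis, amp * gamma^2 / ((axis - center)^2 + gamma^2), "raman")
}

# Regression design with informative variable windows planted on a latent
# response; everything else is noise.
planted_signal_matrix <- function(n = 60, n_win = 20, width = 5,
                                  informative = c(3, 9, 15), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * n_win * width), n)
  y <- rnorm(n, 35, 20)
  z <- (y - mean(y)) / sd(y)
  for (w in informative) {
    cols <- ((w - 1) * width + 1):(w * width)
    X[, cols] <- X[, cols] * 0.3 + outer(z, runif(width, 0.8, 1.2))
  }
  list(X = X, y = y, informative = informative)
}

# Cheap cohort proxy for modelling tests: one FTIR point spectrum per
# (donor, structure), individually baseline-corrected, cropped and SNV'd.
quick_ftir_cohort <- function(seed, n_donors = 40) {
  d <- make_cohort(n_donors, 0, 74, seed = seed)
  bands <- default_band_table("ftir")
  sp <- vector("list", n_donors * 3)
  k <- 0
  for (i in seq_len(n_donors)) {
    de <- osteospectra:::donor_band_effect(nrow(bands), 0.05,
                                           derive_seed(seed, 1L, i))
    for (st in d$structures) {
      k <- k + 1
      e <- list(donor_id = d$donors$donor_id[i], age = d$donors$age[i],
                structure = st, replicate = 1)
      s <- generate_spectrum(e, "ftir",
                             seed = derive_seed(seed, 5L, i,
                                                match(st, d$structures)),
                             donor_effect = de)
      sp[[k]] <- snv(crop_fingerprint(polynomial_baseline_correct(s, 2)))
    }
  }
  assemble_data_matrix(sp)
}

# Full image-based cohorts are expensive; build each once per test run.
.cohort_cache <- new.env(parent = emptyenv())

full_cohort_design <- function() {
  if (is.null(.cohort_cache$design)) {
    .cohort_cache$design <- make_cohort(40, 0, 74, seed = 1)
  }
  .cohort_cache$design
}

full_cohort_ftir <- function() {
  if (is.null(.cohort_cache$ftir)) {
    .cohort_cache$ftir <- cohort_ftir_averages(full_cohort_design(), seed = 1)
  }
  .cohort_cache$ftir
}

full_cohort_raman <- function() {
  if (is.null(.cohort_cache$raman)) {
    .cohort_cache$raman <- cohort_raman_averages(full_cohort_design(), seed = 1)
  }
  .cohort_cache$raman
}

test_entry <- function(age, replicate = 1) {
  list(donor_id = "T01", age = age, structure = "diploe",
       replicate = replicate)
}
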