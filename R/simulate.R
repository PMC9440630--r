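#' Noise and artifact model for simulated acquisitions
#'
#' Bundles the stochastic components layered on top of the noiseless band
#' model: additive detector noise, a smooth polynomial baseline with
#' per-acquisition jitter, a broad fluorescence background (Raman only),
#' cosmic spikes (Raman only), out-of-threshold FPA pixels (FTIR images
#' only), lognormal per-pixel / per-replicate intensity jitter emulating
#' scatter and focus variation, and lognormal per-donor band-amplitude
#' variation creating between-donor biological spread.
#'
#' Defaults are deliberately moderate: strong enough that every preprocessing
#' step has real work to do, weak enough that the age signal dominates, which
#' is the regime the downstream statistics assume.
#'
#' @param modality `"ftir"` or `"raman"`.
#' @param additive_sd Gaussian detector noise sd (absorbance / counts).
#' @param baseline_coef Baseline polynomial coefficients (constant first) on
#'   the axis rescaled to `[0, 1]`; order <= 3.
#' @param baseline_jitter sd of the per-acquisition perturbation of each
#'   baseline coefficient.
#' @param fluorescence_amplitude Mean amplitude of the broad fluorescence
#'   background (Raman; 0 disables).
#' @param spike_rate Poisson mean number of cosmic spikes per spectrum.
#' @param spike_amp_range Range (min, max) of spike amplitudes, counts.
#' @param bad_pixel_fraction Fraction of FPA pixels planted as bad
#'   (half dead / half over-absorbing).
#' @param pixel_jitter_sdlog Lognormal sdlog of the per-pixel multiplier.
#' @param replicate_jitter_sdlog Lognormal sdlog of the per-spectrum
#'   multiplier.
#' @param donor_band_sdlog Lognormal sdlog of per-donor, per-band amplitude
#'   variation.
#' @param replicate_band_sdlog Lognormal sdlog of per-acquisition, per-band
#'   amplitude variation.
#' @return An object of class `"noise_model"` (a list).
#' @export
noise_model <- function(modality = c("ftir", "raman"),
                        additive_sd = NULL,
                        baseline_coef = NULL,
                        baseline_jitter = NULL,
                        fluorescence_amplitude = NULL,
                        spike_rate = NULL,
                        spike_amp_range = NULL,
                        bad_pixel_fraction = NULL,
                        pixel_jitter_sdlog = NULL,
                        replicate_jitter_sdlog = NULL,
                        donor_band_sdlog = NULL,
                        replicate_band_sdlog = NULL) {
  modality <- match.arg(modality)
  def <- if (modality == "ftir") {
    list(additive_sd = 0.003,
         baseline_coef = c(0.02, 0.015, 0.008),
         baseline_jitter = 0.004,
         fluorescence_amplitude = 0,
         spike_rate = 0,
         spike_amp_range = c(0, 0),
         bad_pixel_fraction = 0.02,
         pixel_jitter_sdlog = 0.08,
         replicate_jitter_sdlog = 0.03,
         donor_band_sdlog = 0.05,
         replicate_band_sdlog = 0.02)
  } else {
    list(additive_sd = 8,
         baseline_coef = c(0, 0, 0),
         baseline_jitter = 0,
         fluorescence_amplitude = 400,
         spike_rate = 0.5,
         spike_amp_range = c(800, 4000),
         bad_pixel_fraction = 0,
         pixel_jitter_sdlog = 0,
         replicate_jitter_sdlog = 0.04,
         donor_band_sdlog = 0.05,
         replicate_band_sdlog = 0.02)
  }
  user <- list(additive_sd = additive_sd, baseline_coef = baseline_coef,
               baseline_jitter = baseline_jitter,
               fluorescence_amplitude = fluorescence_amplitude,
               spike_rate = spike_rate, spike_amp_range = spike_amp_range,
               bad_pixel_fraction = bad_pixel_fraction,
               pixel_jitter_sdlog = pixel_jitter_sdlog,
               replicate_jitter_sdlog = replicate_jitter_sdlog,
               donor_band_sdlog = donor_band_sdlog,
               replicate_band_sdlog = replicate_band_sdlog)
  for (nm in names(user)) if (!is.null(user[[nm]])) def[[nm]] <- user[[nm]]
  rates <- c(def$additive_sd, def$baseline_jitter, def$fluorescence_amplitude,
             def$spike_rate, def$bad_pixel_fraction, def$pixel_jitter_sdlog,
             def$replicate_jitter_sdlog, def$donor_band_sdlog,
             def$replicate_band_sdlog)
  if (any(rates < 0)) stop("noise rates and sds must be >= 0")
  if (length(def$baseline_coef) > 4) stop("baseline order must be <= 3")
  def$modality <- modality
  class(def) <- "noise_model"
  def
}

#' A noise model with every stochastic component switched off
#'
#' @param modality `"ftir"` or `"raman"`.
#' @return A `"noise_model"` producing deterministic, artifact-free spectra.
#' @export
zero_noise_model <- function(modality = c("ftir", "raman")) {
  noise_model(match.arg(modality), additive_sd = 0,
              baseline_coef = c(0, 0, 0), baseline_jitter = 0,
              fluorescence_amplitude = 0, spike_rate = 0,
              spike_amp_range = c(0, 0), bad_pixel_fraction = 0,
              pixel_jitter_sdlog = 0, replicate_jitter_sdlog = 0,
              donor_band_sdlog = 0, replicate_band_sdlog = 0)
}

# Smooth decreasing fluorescence shape on u in [0, 1] (unit amplitude at u=0).
fluorescence_shape <- function(u) 1 - 0.9 * u + 0.35 * u^2 - 0.05 * u^3

# Evaluate a polynomial baseline (constant-first coefficients) on the axis
# rescaled to [0, 1].
eval_baseline <- function(axis, coef) {
  u <- (axis - min(axis)) / diff(range(axis))
  drop(outer(u, seq_along(coef) - 1, "^") %*% coef)
}

# Per-donor band-amplitude multipliers, deterministic in (seed, donor index).
donor_band_effect <- function(n_bands, sdlog, seed) {
  if (sdlog <= 0) return(rep(1, n_bands))
  local_seed(seed, stats::rlnorm(n_bands, 0, sdlog))
}

#' Simulate one vibrational spectrum
#'
#' Builds the noiseless band superposition at the donor's age and layers the
#' configured artifacts on top: intensity = sum of band profiles x age
#' amplitudes (x donor and replicate jitter) + polynomial baseline
#' (+ fluorescence and cosmic spikes for Raman) + additive noise.
#'
#' The returned spectrum carries a `"truth"` attribute with the exact band
#' amplitudes used, the spike positions and the baseline realisation, so
#' preprocessing steps can be tested against ground truth.
#'
#' @param entry A list or one-row data frame with `donor_id`, `age`,
#'   `structure`, `replicate`.
#' @param modality `"ftir"` or `"raman"`.
#' @param bands Band table ([default_band_table()]).
#' @param responses Named list of age responses ([default_age_responses()]).
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical inputs + seed give bit-identical output.
#' @param donor_effect Optional per-band multiplier vector shared by all
#'   spectra of one donor (computed by the cohort simulators); `NULL` = 1.
#' @param axis Optional custom wavenumber axis (defaults to the modality's
#'   standard acquisition axis).
#' @return A [spectrum()] with attached ground truth.
#' @export
generate_spectrum <- function(entry, modality = c("ftir", "raman"),
                              bands = default_band_table(modality),
                              responses = default_age_responses(),
                              noise = noise_model(modality),
                              seed = 1, donor_effect = NULL, axis = NULL) {
  modality <- match.arg(modality)
  if (is.null(axis)) axis <- default_axis(modality)
  if (nrow(bands) == 0) stop("band table is empty")
  validate_bands(bands, axis)
  if (is.null(donor_effect)) donor_effect <- rep(1, nrow(bands))

  profiles <- band_profiles(axis, bands)
  base_amp <- band_amplitudes_at_age(bands, entry$age, responses)

  local_seed(seed, {
    rep_band <- if (noise$replicate_band_sdlog > 0)
      stats::rlnorm(nrow(bands), 0, noise$replicate_band_sdlog) else rep(1, nrow(bands))
    rep_scale <- if (noise$replicate_jitter_sdlog > 0)
      stats::rlnorm(1, 0, noise$replicate_jitter_sdlog) else 1
    amps <- base_amp * donor_effect * rep_band * rep_scale
    signal <- drop(profiles %*% amps)

    bcoef <- noise$baseline_coef +
      if (noise$baseline_jitter > 0)
        stats::rnorm(length(noise$baseline_coef), 0, noise$baseline_jitter)
      else 0
    baseline <- eval_baseline(axis, bcoef)

    fluor <- 0
    if (noise$fluorescence_amplitude > 0) {
      a <- noise$fluorescence_amplitude * stats::rlnorm(1, 0, 0.2)
      u <- (axis - min(axis)) / diff(range(axis))
      fluor <- a * fluorescence_shape(u)
    }

    spikes <- numeric(length(axis))
    spike_idx <- integer(0)
    if (noise$spike_rate > 0) {
      n_spk <- stats::rpois(1, noise$spike_rate)
      if (n_spk > 0) {
        spike_idx <- sample.int(length(axis), n_spk)
        spikes[spike_idx] <- stats::runif(n_spk, noise$spike_amp_range[1],
                                          noise$spike_amp_range[2])
      }
    }

    eps <- if (noise$additive_sd > 0)
      stats::rnorm(length(axis), 0, noise$additive_sd) else 0

    s <- spectrum(axis, signal + baseline + fluor + spikes + eps,
                  modality = modality, donor_id = entry$donor_id,
                  age = entry$age, structure = entry$structure,
                  replicate = entry$replicate)
    attr(s, "truth") <- list(amplitudes = stats::setNames(amps, bands$name),
                             spike_idx = sort(spike_idx),
                             baseline_coef = bcoef)
    s
  })
}

#' Simulate one FTIR focal-plane-array image
#'
#' Generates the 32 x 32 = 1024 pixel spectra of one FPA acquisition as a
#' single matrix operation: shared band amplitudes at the donor's age,
#' lognormal per-pixel intensity jitter, per-pixel baseline jitter and
#' additive noise. A configured fraction of pixels is planted as bad --
#' half "dead" (all-zero spectrum, failing the lower quality threshold) and
#' half over-absorbing (signal rescaled so the 1475-1724 cm^-1 window
#' maximum lands above the 0.3 ceiling) -- so the downstream quality filter
#' has ground truth to be checked against.
#'
#' @inheritParams generate_spectrum
#' @param n_pixels Number of detector pixels (default 1024).
#' @return A [spectral_image()]; `$bad_pixels` lists the planted bad pixel
#'   indices, and the `"truth"` attribute records their type.
#' @export
generate_ftir_image <- function(entry, bands = default_band_table("ftir"),
                                responses = default_age_responses(),
                                noise = noise_model("ftir"), seed = 1,
                                donor_effect = NULL, n_pixels = 1024L) {
  axis <- ftir_axis()
  if (nrow(bands) == 0) stop("band table is empty")
  validate_bands(bands, axis)
  if (is.null(donor_effect)) donor_effect <- rep(1, nrow(bands))
  profiles <- band_profiles(axis, bands)
  base_amp <- band_amplitudes_at_age(bands, entry$age, responses)
  qc_win <- which(axis >= 1475 & axis <= 1724)

  local_seed(seed, {
    img_band <- if (noise$replicate_band_sdlog > 0)
      stats::rlnorm(nrow(bands), 0, noise$replicate_band_sdlog) else rep(1, nrow(bands))
    amps <- base_amp * donor_effect * img_band
    clean <- drop(profiles %*% amps)            # shared noiseless pixel signal

    pix <- if (noise$pixel_jitter_sdlog > 0)
      stats::rlnorm(n_pixels, 0, noise$pixel_jitter_sdlog) else rep(1, n_pixels)
    signal <- tcrossprod(clean, pix)            # channels x pixels

    # bad pixels: dead (zero) and hot (window max pushed above threshold).
    # Hot pixels are scaled against the baseline-corrected signal profile so
    # they still exceed the ceiling after the preprocessing baseline fit.
    n_bad <- round(noise$bad_pixel_fraction * n_pixels)
    bad <- sort(sample.int(n_pixels, n_bad))
    n_dead <- floor(n_bad / 2)
    dead <- bad[seq_len(n_dead)]
    hot <- setdiff(bad, dead)
    if (length(hot) > 0) {
      corr_clean <- drop(baseline_correct_matrix(axis, cbind(clean), order = 2))
      corr_max <- max(corr_clean[qc_win])
      targets <- stats::runif(length(hot), 0.35, 0.6)
      for (i in seq_along(hot)) {
        p <- hot[i]
        signal[, p] <- signal[, p] * targets[i] / (pix[hot[i]] * corr_max)
      }
    }

    # per-image baseline, lightly jittered per pixel
    bcoef <- noise$baseline_coef +
      if (noise$baseline_jitter > 0)
        stats::rnorm(length(noise$baseline_coef), 0, noise$baseline_jitter)
      else 0
    u <- (axis - min(axis)) / diff(range(axis))
    basis <- outer(u, seq_along(bcoef) - 1, "^")
    pix_coef <- matrix(bcoef, nrow = length(bcoef), ncol = n_pixels) +
      if (noise$baseline_jitter > 0)
        matrix(stats::rnorm(length(bcoef) * n_pixels, 0,
                            noise$baseline_jitter / 4),
               nrow = length(bcoef)) else 0
    baseline <- basis %*% pix_coef

    eps <- if (noise$additive_sd > 0)
      matrix(stats::rnorm(length(axis) * n_pixels, 0, noise$additive_sd),
             nrow = length(axis)) else 0

    intens <- signal + baseline + eps
    if (length(dead) > 0) intens[, dead] <- 0

    img <- spectral_image(axis, intens, donor_id = entry$donor_id,
                          age = entry$age, structure = entry$structure,
                          replicate = entry$replicate, bad_pixels = bad)
    attr(img, "truth") <- list(amplitudes = stats::setNames(amps, bands$name),
                               dead_pixels = dead, hot_pixels = hot,
                               pixel_jitter = pix, baseline_coef = bcoef)
    img
  })
}

# Enumerate the (donor, structure, replicate) acquisition plan of a design.
acquisition_plan <- function(design, modality) {
  n_rep <- if (modality == "ftir") design$ftir_images_per_structure
           else design$raman_spectra_per_structure
  expand.grid(replicate = seq_len(n_rep),
              structure = design$structures,
              donor_idx = seq_len(nrow(design$donors)),
              stringsAsFactors = FALSE)[, 3:1]
}

#' Simulate the Raman point spectra of a whole cohort
#'
#' Three point spectra per (donor, structure), seeded hierarchically so any
#' subset is reproducible in isolation.
#'
#' @param design A [make_cohort()] design.
#' @inheritParams generate_spectrum
#' @return List of [spectrum()] objects
#'   (`n_donors x 3 structures x 3 replicates`).
#' @export
simulate_raman_cohort <- function(design, bands = default_band_table("raman"),
                                  responses = default_age_responses(),
                                  noise = noise_model("raman"), seed = 1) {
  plan <- acquisition_plan(design, "raman")
  struct_idx <- match(plan$structure, design$structures)
  lapply(seq_len(nrow(plan)), function(k) {
    i <- plan$donor_idx[k]
    de <- donor_band_effect(nrow(bands), noise$donor_band_sdlog,
                            derive_seed(seed, 2L, i))
    entry <- list(donor_id = design$donors$donor_id[i],
                  age = design$donors$age[i],
                  structure = plan$structure[k],
                  replicate = plan$replicate[k])
    generate_spectrum(entry, "raman", bands, responses, noise,
                      seed = derive_seed(seed, 2L, i, struct_idx[k],
                                         plan$replicate[k]),
                      donor_effect = de)
  })
}

#' Simulate the FTIR FPA images of one donor structure
#'
#' @param design A [make_cohort()] design.
#' @param donor_idx Donor row index in `design$donors`.
#' @param structure Structure name.
#' @inheritParams generate_spectrum
#' @return List of [spectral_image()]s (2 per structure by design).
#' @export
simulate_ftir_structure <- function(design, donor_idx, structure,
                                    bands = default_band_table("ftir"),
                                    responses = default_age_responses(),
                                    noise = noise_model("ftir"), seed = 1) {
  de <- donor_band_effect(nrow(bands), noise$donor_band_sdlog,
                          derive_seed(seed, 1L, donor_idx))
  s_idx <- match(structure, design$structures)
  lapply(seq_len(design$ftir_images_per_structure), function(r) {
    entry <- list(donor_id = design$donors$donor_id[donor_idx],
                  age = design$donors$age[donor_idx],
                  structure = structure, replicate = r)
    generate_ftir_image(entry, bands, responses, noise,
                        seed = derive_seed(seed, 1L, donor_idx, s_idx, r),
                        donor_effect = de)
  })
}

#' Closed-form noiseless outcome set-points of the generator
#'
#' Evaluates, without simulating a spectrum, the outcome panel a noiseless,
#' baseline-free acquisition would carry at a given age: band-window areas
#' from the exact pseudo-Voigt window integrals (including tails of
#' neighbouring bands), intensity ratios from the profile sums at the probe
#' wavenumbers, and Raman crystallinity from the full width at half maximum
#' of the composite phosphate nu1 profile evaluated on a 0.01 cm^-1 grid.
#' These are the ground-truth values the measurement chain is tested against.
#'
#' @param age Donor age, years.
#' @param modality `"ftir"` or `"raman"`.
#' @param bands,responses Band table and response set.
#' @return Named list `mineral_matrix`, `carbonate_phosphate`,
#'   `crystallinity`, `collagen_maturity`.
#' @export
expected_outcomes <- function(age, modality = c("ftir", "raman"),
                              bands = default_band_table(modality),
                              responses = default_age_responses()) {
  modality <- match.arg(modality)
  amps <- band_amplitudes_at_age(bands, age, responses)
  wmass <- function(lo, hi) {
    sum(amps * vapply(seq_len(nrow(bands)), function(j) {
      band_window_mass(bands$center[j], bands$sigma[j], bands$mix[j], lo, hi)
    }, numeric(1)))
  }
  profile_at <- function(x) {
    sum(amps * drop(band_profiles(x, bands)))
  }
  if (modality == "ftir") {
    list(mineral_matrix = wmass(900, 1200) / wmass(1592, 1712),
         carbonate_phosphate = wmass(850, 890) / wmass(900, 1200),
         crystallinity = profile_at(1030) / profile_at(1020),
         collagen_maturity = profile_at(1660) / profile_at(1690))
  } else {
    grid <- seq(830, 1080, by = 0.01)   # matches the fwhm() flank region
    prof <- drop(band_profiles(grid, bands) %*% amps)
    pk <- which.max(prof)
    half <- min(prof) + (prof[pk] - min(prof)) / 2
    left <- max(which(prof[seq_len(pk)] < half))
    right <- pk + min(which(prof[-seq_len(pk)] < half)) - 1
    fw <- grid[right] - grid[left]
    list(mineral_matrix = wmass(410, 460) / wmass(1215, 1300),
         carbonate_phosphate = wmass(1050, 1100) / wmass(930, 980),
         crystallinity = 1 / fw,
         collagen_maturity = profile_at(1660) / profile_at(1690))
  }
}
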