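#' Construct a single vibrational spectrum
#'
#' A spectrum couples a strictly increasing wavenumber axis with an intensity
#' vector (absorbance for FTIR, counts for Raman) and carries the acquisition
#' metadata used throughout the pipeline: donor, donor age, anatomical
#' structure (lamina externa, diploe or lamina interna of the cranial vault)
#' and replicate index.
#'
#' @param wavenumber Numeric vector of wavenumbers (cm^-1). May be given in
#'   descending (instrument) order; it is stored ascending and the intensities
#'   are reordered to match.
#' @param intensity Numeric vector, same length as `wavenumber`.
#' @param modality `"ftir"` or `"raman"`.
#' @param donor_id Donor identifier (character or integer).
#' @param age Donor chronological age in years.
#' @param structure One of `"lamina_externa"`, `"diploe"`, `"lamina_interna"`,
#'   or `NA` for synthetic test spectra.
#' @param replicate Replicate index within (donor, structure), or `"mean"` for
#'   a structure-averaged spectrum.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavenumber, intensity, modality = c("ftir", "raman"),
                     donor_id = NA_character_, age = NA_real_,
                     structure = NA_character_, replicate = NA) {
  modality <- match.arg(modality)
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity)) {
    stop("wavenumber and intensity must have equal length")
  }
  if (length(wavenumber) < 2L) stop("a spectrum needs at least two channels")
  d <- diff(wavenumber)
  if (all(d < 0)) {           # instrument order: high -> low wavenumber
    wavenumber <- rev(wavenumber)
    intensity <- rev(intensity)
  } else if (!all(d > 0)) {
    stop("wavenumber axis must be strictly monotone")
  }
  structure(
    list(wavenumber = wavenumber, intensity = intensity,
         modality = modality, donor_id = donor_id, age = as.numeric(age),
         structure = structure, replicate = replicate),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> %s | %d channels, %.0f-%.0f cm^-1 | donor %s age %s | %s rep %s\n",
    toupper(x$modality), length(x$wavenumber),
    min(x$wavenumber), max(x$wavenumber),
    x$donor_id, format(x$age), x$structure, format(x$replicate)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Standard FTIR acquisition axis
#'
#' The FTIR axis runs 3850 down to 400 cm^-1 at 4 cm^-1 resolution; it is
#' returned ascending (402 to 3850 cm^-1, 863 channels).
#' @return Numeric vector of wavenumbers.
#' @export
ftir_axis <- function() seq(402, 3850, by = 4)

#' Standard Raman acquisition axis
#'
#' 2000 down to 300 cm^-1 at 1 cm^-1 resolution, returned ascending
#' (1701 channels).
#' @return Numeric vector of wavenumbers.
#' @export
raman_axis <- function() seq(300, 2000, by = 1)

default_axis <- function(modality) {
  switch(modality, ftir = ftir_axis(), raman = raman_axis(),
         stop("unknown modality: ", modality))
}

#' Construct a focal-plane-array spectral image
#'
#' One FTIR FPA acquisition: a 32 x 32 pixel grid, every pixel holding a full
#' spectrum on a shared axis. Intensities are stored as a channels x pixels
#' matrix.
#'
#' @param wavenumber Shared ascending wavenumber axis.
#' @param intensities Numeric matrix, `length(wavenumber)` rows, one column
#'   per pixel (1024 for the standard 32 x 32 detector).
#' @param donor_id,age,structure,replicate Acquisition metadata.
#' @param bad_pixels Integer vector of pixel indices planted as bad by the
#'   simulator (empty for real data).
#' @return An object of class `"spectral_image"`.
#' @export
spectral_image <- function(wavenumber, intensities, donor_id = NA_character_,
                           age = NA_real_, structure = NA_character_,
                           replicate = NA, bad_pixels = integer(0)) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(wavenumber)) {
    stop("intensity matrix must have one row per wavenumber channel")
  }
  structure(
    list(wavenumber = as.numeric(wavenumber), intensities = intensities,
         donor_id = donor_id, age = as.numeric(age), structure = structure,
         replicate = replicate, bad_pixels = as.integer(bad_pixels)),
    class = "spectral_image"
  )
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf(
    "<spectral_image> %d pixels x %d channels | donor %s age %s | %s rep %s | %d planted bad\n",
    ncol(x$intensities), nrow(x$intensities), x$donor_id, format(x$age),
    x$structure, format(x$replicate), length(x$bad_pixels)))
  invisible(x)
}

#' Extract one pixel of a spectral image as a spectrum
#'
#' @param image A `spectral_image`.
#' @param pixel Pixel (column) index.
#' @return A `spectrum`.
#' @export
image_pixel <- function(image, pixel) {
  stopifnot(inherits(image, "spectral_image"))
  spectrum(image$wavenumber, image$intensities[, pixel], modality = "ftir",
           donor_id = image$donor_id, age = image$age,
           structure = image$structure, replicate = pixel)
}

# Run code with a local RNG state so callers' streams are untouched.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed
#'
#' Hierarchical seeding: every (donor, structure, replicate) draws its own
#' seed deterministically from the master seed, so any subset of a cohort can
#' be regenerated in isolation.
#'
#' @param seed Master seed (integer).
#' @param ... Further integer components (donor index, structure index,
#'   replicate index, ...).
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 48271 + (as.numeric(p) %% 2147483647)) %% 2147483647
  }
  as.integer(h) + 1L
}
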