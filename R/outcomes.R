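#' Define a band window
#'
#' A closed wavenumber interval used for band quantification, with the
#' quantification mode attached.
#'
#' @param name Window label.
#' @param lo,hi Bounds in cm^-1 (`lo <= hi`; equal for `intensity_at`).
#' @param mode `"area"`, `"intensity_at"` or `"fwhm_of"`.
#' @return A list of class `"band_window"`.
#' @export
band_window <- function(name, lo, hi = lo,
                        mode = c("area", "intensity_at", "fwhm_of")) {
  mode <- match.arg(mode)
  stopifnot(lo <= hi)
  if (mode == "intensity_at" && lo != hi) {
    stop("intensity_at windows must have lo == hi")
  }
  structure(list(name = name, lo = lo, hi = hi, mode = mode),
            class = "band_window")
}

# Indices of the axis channels covering [lo, hi], snapped outward to the
# nearest grid channel so the window never shrinks on a discrete grid.
window_channels <- function(axis, lo, hi) {
  i_lo <- if (any(axis <= lo)) max(which(axis <= lo)) else 1L
  i_hi <- if (any(axis >= hi)) min(which(axis >= hi)) else length(axis)
  seq(i_lo, i_hi)
}

#' Integrated band area over a window
#'
#' Trapezoidal integral of the (already baseline-corrected) signal over the
#' closed window, with the window endpoints snapped outward to the grid.
#' No local baseline is subtracted; SNV-transformed spectra are integrated
#' as the signed signal.
#'
#' @param s A [spectrum()].
#' @param w A [band_window()] or numeric `c(lo, hi)`.
#' @return Area in intensity x cm^-1.
#' @export
band_area <- function(s, w) {
  stopifnot(is_spectrum(s))
  if (inherits(w, "band_window")) w <- c(w$lo, w$hi)
  if (w[1] < min(s$wavenumber) || w[2] > max(s$wavenumber)) {
    stop("band window outside the spectral axis")
  }
  idx <- window_channels(s$wavenumber, w[1], w[2])
  if (length(idx) < 2) stop("band window covers fewer than 2 channels")
  x <- s$wavenumber[idx]
  y <- s$intensity[idx]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Interpolated intensity at a wavenumber
#'
#' Linear interpolation between the two bracketing channels; probes such as
#' 1030 cm^-1 do not in general coincide with the 4 cm^-1 FTIR grid.
#'
#' @param s A [spectrum()].
#' @param at Wavenumber, cm^-1 (inside the axis range).
#' @return Interpolated intensity.
#' @export
band_intensity <- function(s, at) {
  stopifnot(is_spectrum(s))
  if (at < min(s$wavenumber) || at > max(s$wavenumber)) {
    stop("requested wavenumber requires extrapolation")
  }
  stats::approx(s$wavenumber, s$intensity, xout = at)$y
}

#' Full width at half maximum of a peak
#'
#' Locates the intensity maximum inside the search window and finds the two
#' half-maximum crossings by linear interpolation on the flanks. The
#' half-maximum level is taken relative to the local base (minimum intensity
#' over the flank search region), which reduces to the usual definition on
#' baseline-free peaks.
#'
#' @param s A [spectrum()].
#' @param search A [band_window()] or numeric `c(lo, hi)` bracketing the peak
#'   (930-980 cm^-1 for the Raman phosphate nu1 peak).
#' @param flank_factor How far beyond the search window (in multiples of its
#'   width) the flanks may extend when hunting the crossings.
#' @return Width in cm^-1.
#' @export
fwhm <- function(s, search, flank_factor = 2) {
  stopifnot(is_spectrum(s))
  if (inherits(search, "band_window")) search <- c(search$lo, search$hi)
  idx <- which(s$wavenumber >= search[1] & s$wavenumber <= search[2])
  if (length(idx) < 3) stop("search window too narrow for peak location")
  pk_local <- which.max(s$intensity[idx])
  if (pk_local == 1 || pk_local == length(idx)) {
    stop("no interior local maximum inside the search window")
  }
  pk <- idx[pk_local]
  width <- diff(search)
  ext <- which(s$wavenumber >= search[1] - flank_factor * width &
               s$wavenumber <= search[2] + flank_factor * width)
  base <- min(s$intensity[ext])
  half <- base + (s$intensity[pk] - base) / 2
  x <- s$wavenumber
  y <- s$intensity
  cross <- function(side_idx) {
    below <- which(y[side_idx] < half)
    if (length(below) == 0) {
      stop("half-maximum not bracketed inside the flank region (peak ",
           "at ", x[pk], " cm^-1): widen flank_factor")
    }
    below
  }
  left_idx <- rev(ext[ext <= pk])     # walk outward from the peak
  lb <- cross(left_idx)[1]
  i2 <- left_idx[lb]; i1 <- left_idx[lb - 1]
  x_left <- x[i2] + (half - y[i2]) * (x[i1] - x[i2]) / (y[i1] - y[i2])
  right_idx <- ext[ext >= pk]
  rb <- cross(right_idx)[1]
  i2 <- right_idx[rb]; i1 <- right_idx[rb - 1]
  x_right <- x[i1] + (half - y[i1]) * (x[i2] - x[i1]) / (y[i2] - y[i1])
  x_right - x_left
}

#' Compute the four bone-quality outcomes of one spectrum
#'
#' FTIR: mineral/matrix = area(900-1200)/area(1592-1712);
#' carbonate/phosphate = area(850-890)/area(900-1200);
#' crystallinity = intensity(1030)/intensity(1020);
#' collagen maturity = intensity(1660)/intensity(1690).
#' Raman: mineral/matrix = area(410-460)/area(1215-1300);
#' carbonate/phosphate = area(1050-1100)/area(930-980);
#' crystallinity = 1/FWHM of the phosphate nu1 peak (930-980);
#' collagen maturity = intensity(1660)/intensity(1690).
#' All outcomes are ratios and hence invariant to positive rescaling of the
#' spectrum.
#'
#' SNV leaves spectra mean-zero, so small-band areas (notably the FTIR
#' carbonate window) become sign-indefinite on SNV-processed input;
#' `shift = "min"` re-anchors the spectrum at zero (subtracting its minimum
#' over the retained axis) before quantification, restoring positive ratios
#' while preserving scale invariance.
#'
#' @param s A preprocessed, structure-averaged [spectrum()].
#' @param shift `"none"` (quantify the signed signal as-is) or `"min"`
#'   (anchor the spectrum minimum at zero first).
#' @return One-row data frame (class `"outcome_panel"`): `donor_id`, `age`,
#'   `structure`, `modality`, `mineral_matrix`, `carbonate_phosphate`,
#'   `crystallinity`, `collagen_maturity`.
#' @export
compute_outcomes <- function(s, shift = c("none", "min")) {
  stopifnot(is_spectrum(s))
  shift <- match.arg(shift)
  if (shift == "min") s$intensity <- s$intensity - min(s$intensity)
  wrap <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      stop(what, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  if (s$modality == "ftir") {
    mm <- wrap(band_area(s, c(900, 1200)) / band_area(s, c(1592, 1712)),
               "mineral_matrix")
    cp <- wrap(band_area(s, c(850, 890)) / band_area(s, c(900, 1200)),
               "carbonate_phosphate")
    cr <- wrap(band_intensity(s, 1030) / band_intensity(s, 1020),
               "crystallinity")
    cm <- wrap(band_intensity(s, 1660) / band_intensity(s, 1690),
               "collagen_maturity")
  } else {
    mm <- wrap(band_area(s, c(410, 460)) / band_area(s, c(1215, 1300)),
               "mineral_matrix")
    cp <- wrap(band_area(s, c(1050, 1100)) / band_area(s, c(930, 980)),
               "carbonate_phosphate")
    cr <- wrap(1 / fwhm(s, c(930, 980)), "crystallinity")
    cm <- wrap(band_intensity(s, 1660) / band_intensity(s, 1690),
               "collagen_maturity")
  }
  out <- data.frame(donor_id = s$donor_id, age = s$age,
                    structure = s$structure, modality = s$modality,
                    mineral_matrix = mm, carbonate_phosphate = cp,
                    crystallinity = cr, collagen_maturity = cm,
                    stringsAsFactors = FALSE)
  class(out) <- c("outcome_panel", class(out))
  out
}

#' Quantify every primary band of a spectrum
#'
#' Reports the integrated areas of all primary band windows of the
#' modality's assignment table (including bands such as amide II that feed
#' no outcome ratio but matter for loading interpretation).
#'
#' @param s A [spectrum()].
#' @return Data frame `band`, `lo`, `hi`, `area`.
#' @export
band_report <- function(s) {
  stopifnot(is_spectrum(s))
  tab <- if (s$modality == "ftir") {
    data.frame(band = c("co3_v2", "po4_v1v3", "amide_iii", "amide_ii",
                        "amide_i"),
               lo = c(850, 900, 1210, 1510, 1592),
               hi = c(890, 1200, 1320, 1590, 1712))
  } else {
    data.frame(band = c("po4_v2", "po4_v1", "co3_v1_po4_v3", "amide_iii",
                        "amide_i"),
               lo = c(410, 930, 1050, 1215, 1620),
               hi = c(460, 980, 1100, 1300, 1700))
  }
  tab$area <- vapply(seq_len(nrow(tab)), function(i) {
    band_area(s, c(tab$lo[i], tab$hi[i]))
  }, numeric(1))
  tab
}

#' Outcome table of a cohort
#'
#' Stacks [compute_outcomes()] panels of a list of structure-averaged
#' spectra into one tidy table with the age stage attached.
#'
#' @param avg_spectra List of averaged [spectrum()]s (one modality or mixed).
#' @param shift Zero-anchoring mode passed to [compute_outcomes()];
#'   default `"min"`, appropriate for SNV-processed spectra.
#' @return Data frame, one row per (donor, structure, modality).
#' @export
cohort_outcomes <- function(avg_spectra, shift = "min") {
  out <- do.call(rbind, lapply(avg_spectra, compute_outcomes, shift = shift))
  out$age_stage <- assign_age_stage(out$age)
  class(out) <- "data.frame"
  out
}

#' Pivot an outcome table to tidy (long) form
#'
#' @param outcomes A [cohort_outcomes()] table.
#' @return Data frame `donor_id`, `age`, `age_stage`, `structure`,
#'   `modality`, `outcome`, `value`.
#' @export
outcomes_long <- function(outcomes) {
  vars <- c("mineral_matrix", "carbonate_phosphate", "crystallinity",
            "collagen_maturity")
  do.call(rbind, lapply(vars, function(v) {
    data.frame(donor_id = outcomes$donor_id, age = outcomes$age,
               age_stage = outcomes$age_stage,
               structure = outcomes$structure, modality = outcomes$modality,
               outcome = v, value = outcomes[[v]],
               stringsAsFactors = FALSE)
  }))
}
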