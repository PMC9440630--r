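#' Polynomial baseline correction
#'
#' Fits a polynomial of the given order to the spectrum and subtracts it.
#' In iterative mode the fit is repeated with the working spectrum clipped to
#' the current fit (points above the fit are replaced by it) until the
#' maximum change of the fitted baseline falls below `tol` or `max_iter` is
#' reached -- the standard scheme for stripping broad fluorescence from under
#' sharp Raman peaks. FTIR images use a single (non-iterative) order-2 fit.
#'
#' @param s A [spectrum()].
#' @param order Polynomial order (>= 0).
#' @param iterative Re-fit with clipping until convergence?
#' @param max_iter,tol Iteration controls (iterative mode).
#' @return The baseline-corrected spectrum; the fitted baseline is attached
#'   as attribute `"baseline"`.
#' @export
polynomial_baseline_correct <- function(s, order = 2, iterative = FALSE,
                                        max_iter = 100, tol = 1e-6) {
  stopifnot(is_spectrum(s), order >= 0)
  y <- s$intensity
  if (any(!is.finite(y))) stop("non-finite intensities; cannot fit baseline")
  if (length(y) <= order + 1) stop("spectrum too short for the requested order")
  basis <- cbind(1, stats::poly(s$wavenumber, degree = max(order, 1)))
  if (order == 0) basis <- basis[, 1, drop = FALSE]
  else basis <- basis[, seq_len(order + 1), drop = FALSE]
  qr_b <- qr(basis)
  fit_of <- function(v) drop(basis %*% qr.coef(qr_b, v))
  if (!iterative) {
    base <- fit_of(y)
  } else {
    work <- y
    base <- fit_of(work)
    for (it in seq_len(max_iter)) {
      work <- pmin(work, base)
      new_base <- fit_of(work)
      if (max(abs(new_base - base)) < tol) { base <- new_base; break }
      base <- new_base
    }
  }
  out <- s
  out$intensity <- y - base
  attr(out, "baseline") <- base
  out
}

# Order-`order` baseline correction of every column of a channels x pixels
# matrix in one QR solve (used for FPA images).
baseline_correct_matrix <- function(axis, Y, order = 2) {
  basis <- cbind(1, stats::poly(axis, degree = max(order, 1)))
  basis <- basis[, seq_len(order + 1), drop = FALSE]
  Y - basis %*% qr.coef(qr(basis), Y)
}

#' Quality-filter the pixels of an FPA image
#'
#' Applied after baseline correction: a pixel is kept iff the maximum of its
#' spectrum inside the test window satisfies `lo < max <= hi`. The lower
#' bound is exclusive (a flat-zero pixel is a dead detector element) and the
#' upper bound inclusive.
#'
#' @param image A [spectral_image()] (baseline-corrected).
#' @param window Test window in cm^-1, default `c(1475, 1724)`.
#' @param lo,hi Lower (exclusive) and upper (inclusive) absorbance
#'   thresholds, default 0 and 0.3.
#' @return A list with `kept` (the filtered [spectral_image()]) and `report`
#'   (class `"quality_report"`): per-pixel window maxima and pass flags plus
#'   kept/removed counts.
#' @export
quality_filter <- function(image, window = c(1475, 1724), lo = 0, hi = 0.3) {
  stopifnot(inherits(image, "spectral_image"))
  window <- sort(window)
  idx <- which(image$wavenumber >= window[1] & image$wavenumber <= window[2])
  if (length(idx) == 0) stop("quality window lies outside the spectral axis")
  wmax <- apply(image$intensities[idx, , drop = FALSE], 2, max)
  pass <- wmax > lo & wmax <= hi
  kept <- image
  kept$intensities <- image$intensities[, pass, drop = FALSE]
  kept$bad_pixels <- integer(0)
  report <- structure(
    list(window = window, lo = lo, hi = hi,
         window_max = wmax, pass = pass,
         n_kept = sum(pass), n_removed = sum(!pass),
         removed = which(!pass)),
    class = "quality_report")
  list(kept = kept, report = report)
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "<quality_report> window %g-%g cm^-1, thresholds (%g, %g]: kept %d, removed %d\n",
    x$window[1], x$window[2], x$lo, x$hi, x$n_kept, x$n_removed))
  invisible(x)
}

#' Crop a spectrum to the fingerprint region
#'
#' Retains the channels inside the closed interval `[lo, hi]`
#' (800-1800 cm^-1 by default).
#'
#' @param s A [spectrum()].
#' @param lo,hi Window bounds, cm^-1.
#' @return The cropped spectrum.
#' @export
crop_fingerprint <- function(s, lo = 800, hi = 1800) {
  stopifnot(is_spectrum(s), lo <= hi)
  keep <- s$wavenumber >= lo & s$wavenumber <= hi
  if (!any(keep)) stop("crop window contains no channels")
  out <- s
  out$wavenumber <- s$wavenumber[keep]
  out$intensity <- s$intensity[keep]
  out
}

#' Standard normal variate transformation
#'
#' Centers a spectrum to mean 0 and scales it to unit standard deviation
#' (sample sd, n-1 denominator), correcting multiplicative scatter
#' differences between acquisitions.
#'
#' @param s A [spectrum()].
#' @return The transformed spectrum.
#' @export
snv <- function(s) {
  stopifnot(is_spectrum(s))
  sd_y <- stats::sd(s$intensity)
  if (!is.finite(sd_y) || sd_y == 0) {
    stop("constant spectrum: SNV undefined (zero variance)")
  }
  out <- s
  out$intensity <- (s$intensity - mean(s$intensity)) / sd_y
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (default 11 points, order 3).
#' Edges are handled by the fit-matrix transient rows, i.e. polynomial
#' extrapolation of the marginal fits, so the output has the input length
#' and polynomials up to the filter order pass through unchanged.
#'
#' @param s A [spectrum()].
#' @param window Window length in points (odd, `> order`).
#' @param order Polynomial order.
#' @return The smoothed spectrum.
#' @export
sg_smooth <- function(s, window = 11, order = 3) {
  stopifnot(is_spectrum(s))
  if (window %% 2 == 0) stop("Savitzky-Golay window must be odd")
  if (window <= order) stop("window must exceed the polynomial order")
  if (length(s$intensity) < window) stop("spectrum shorter than the window")
  out <- s
  out$intensity <- signal::sgolayfilt(s$intensity, p = order, n = window)
  out
}

#' Remove cosmic spikes
#'
#' Flags points whose residual from a running median exceeds `z_threshold`
#' robust standard deviations (1.4826 x MAD of the residuals) and replaces
#' them by linear interpolation across the neighbouring clean points.
#'
#' @param s A [spectrum()].
#' @param z_threshold Robust z-score cutoff (default 8).
#' @param neighborhood Running-median window in points (odd, default 5).
#' @return The despiked spectrum; attributes `"spike_idx"` and `"n_replaced"`
#'   report what was replaced.
#' @export
despike <- function(s, z_threshold = 8, neighborhood = 5) {
  stopifnot(is_spectrum(s))
  if (neighborhood %% 2 == 0) neighborhood <- neighborhood + 1
  y <- s$intensity
  if (length(y) <= neighborhood) stop("spectrum shorter than the neighborhood")
  med <- stats::runmed(y, k = neighborhood, endrule = "median")
  res <- y - med
  s_rob <- 1.4826 * stats::mad(res, constant = 1)
  out <- s
  if (s_rob == 0) {
    attr(out, "spike_idx") <- integer(0)
    attr(out, "n_replaced") <- 0L
    return(out)
  }
  spikes <- which(abs(res) > z_threshold * s_rob)
  if (length(spikes) > 0 && length(spikes) < length(y)) {
    keep <- setdiff(seq_along(y), spikes)
    y[spikes] <- stats::approx(s$wavenumber[keep], y[keep],
                               xout = s$wavenumber[spikes], rule = 2)$y
  }
  out$intensity <- y
  attr(out, "spike_idx") <- spikes
  attr(out, "n_replaced") <- length(spikes)
  out
}

#' Average replicate spectra of one structure
#'
#' Pointwise arithmetic mean of spectra sharing axis, modality, donor and
#' structure; the result carries the shared metadata with
#' `replicate = "mean"`.
#'
#' @param spectra List of [spectrum()] objects.
#' @return The averaged [spectrum()]; attribute `"n_averaged"` gives the
#'   number of spectra combined.
#' @export
average_structure <- function(spectra) {
  stopifnot(length(spectra) >= 1, all(vapply(spectra, is_spectrum, logical(1))))
  ref <- spectra[[1]]
  for (s in spectra[-1]) {
    if (length(s$wavenumber) != length(ref$wavenumber) ||
        any(s$wavenumber != ref$wavenumber)) {
      stop("cannot average spectra on different axes")
    }
    if (!identical(s$modality, ref$modality)) stop("mixed modalities")
  }
  m <- rowMeans(vapply(spectra, function(s) s$intensity,
                       numeric(length(ref$intensity))))
  out <- spectrum(ref$wavenumber, m, modality = ref$modality,
                  donor_id = ref$donor_id, age = ref$age,
                  structure = ref$structure, replicate = "mean")
  attr(out, "n_averaged") <- length(spectra)
  out
}

#' FTIR preprocessing chain for one structure
#'
#' The full FPA chain: per-pixel polynomial baseline correction (order 2,
#' single fit), quality filtering (window 1475-1724 cm^-1, thresholds
#' 0 < max <= 0.3), fingerprint cropping to 800-1800 cm^-1, per-pixel SNV,
#' then averaging of every kept pixel across the structure's images (2048
#' pixels before screening).
#'
#' @param images List of [spectral_image()]s of one (donor, structure).
#' @param baseline_order Baseline polynomial order (default 2).
#' @param window,lo,hi Quality-filter parameters (see [quality_filter()]).
#' @param crop Fingerprint window, cm^-1.
#' @return The structure-averaged [spectrum()]; attributes `"quality"`
#'   (list of per-image [quality_filter()] reports) and `"n_averaged"`.
#' @export
preprocess_ftir <- function(images, baseline_order = 2,
                            window = c(1475, 1724), lo = 0, hi = 0.3,
                            crop = c(800, 1800)) {
  stopifnot(length(images) >= 1,
            all(vapply(images, inherits, logical(1), "spectral_image")))
  reports <- vector("list", length(images))
  kept_cols <- list()
  axis <- images[[1]]$wavenumber
  for (k in seq_along(images)) {
    img <- images[[k]]
    img$intensities <- baseline_correct_matrix(img$wavenumber,
                                               img$intensities,
                                               order = baseline_order)
    qf <- quality_filter(img, window = window, lo = lo, hi = hi)
    reports[[k]] <- qf$report
    kept_cols[[k]] <- qf$kept$intensities
  }
  Y <- do.call(cbind, kept_cols)
  if (ncol(Y) == 0) stop("no pixel passed the quality filter")
  sel <- axis >= crop[1] & axis <= crop[2]
  Y <- Y[sel, , drop = FALSE]
  Y <- scale(Y)                      # per-pixel SNV (column mean 0, sd 1)
  ref <- images[[1]]
  out <- spectrum(axis[sel], rowMeans(Y), modality = "ftir",
                  donor_id = ref$donor_id, age = ref$age,
                  structure = ref$structure, replicate = "mean")
  attr(out, "quality") <- reports
  attr(out, "n_averaged") <- ncol(Y)
  out
}

#' Raman preprocessing chain for one structure
#'
#' Applies, in the order given by `steps`, Savitzky-Golay smoothing
#' (11 points, order 3), SNV, cosmic-spike removal and iterative third-degree
#' polynomial baseline subtraction to each replicate, then averages the
#' replicates. The default step order (smooth, SNV, despike, baseline) is
#' unusual in placing SNV before baseline subtraction; it is kept
#' configurable (see the package vignette).
#'
#' @param spectra List of replicate [spectrum()]s of one (donor, structure).
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param z_threshold,neighborhood Despiking parameters.
#' @param baseline_order Baseline polynomial order (default 3, iterative).
#' @param max_iter,tol Iterative-baseline controls.
#' @param steps Character vector ordering the steps; any subset/permutation
#'   of `c("sg", "snv", "despike", "baseline")`.
#' @return The structure-averaged [spectrum()].
#' @export
preprocess_raman <- function(spectra, sg_window = 11, sg_order = 3,
                             z_threshold = 8, neighborhood = 5,
                             baseline_order = 3, max_iter = 100, tol = 1e-6,
                             steps = c("sg", "snv", "despike", "baseline")) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, is_spectrum, logical(1))))
  if (!all(steps %in% c("sg", "snv", "despike", "baseline"))) {
    stop("unknown preprocessing step")
  }
  one <- function(s) {
    for (st in steps) {
      s <- switch(st,
        sg = sg_smooth(s, window = sg_window, order = sg_order),
        snv = snv(s),
        despike = despike(s, z_threshold = z_threshold,
                          neighborhood = neighborhood),
        baseline = polynomial_baseline_correct(s, order = baseline_order,
                                               iterative = TRUE,
                                               max_iter = max_iter, tol = tol))
    }
    s
  }
  average_structure(lapply(spectra, one))
}
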