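#' Define one vibrational band
#'
#' Bands are pseudo-Voigt profiles: a convex mixture of a Gaussian and a
#' Lorentzian of equal full width at half maximum. `mix` is the Lorentzian
#' fraction; `mix = 0` gives a pure Gaussian. The Gaussian sigma parameterises
#' the width; the matched Lorentzian half-width is `gamma = sigma * sqrt(2 log 2)`.
#'
#' @param name Band label (e.g. `"po4_v1v3"`).
#' @param center Band center, cm^-1.
#' @param sigma Gaussian sigma, cm^-1 (> 0).
#' @param class One of `"mineral"`, `"organic"`, `"carbonate"`.
#' @param amplitude Base peak amplitude at unit age response (absorbance for
#'   FTIR, counts for Raman).
#' @param mix Lorentzian mixing fraction in `[0, 1]`.
#' @param response Name of the age-response profile applied to this band
#'   (a key of [default_age_responses()], or of a user-supplied response list).
#' @return A one-row data frame; rows from several calls can be `rbind`-ed
#'   into a band table.
#' @export
band_spec <- function(name, center, sigma, class, amplitude,
                      mix = 0.5, response = "flat") {
  stopifnot(sigma > 0, mix >= 0, mix <= 1,
            class %in% c("mineral", "organic", "carbonate"))
  data.frame(name = name, center = center, sigma = sigma, class = class,
             amplitude = amplitude, mix = mix, response = response,
             stringsAsFactors = FALSE)
}

#' Evaluate band profiles on a wavenumber axis
#'
#' @param axis Wavenumber axis.
#' @param bands Band table (rows from [band_spec()]).
#' @return Matrix `length(axis)` x `nrow(bands)` of unit-amplitude profiles
#'   (peak value 1 at the band center).
#' @export
band_profiles <- function(axis, bands) {
  out <- matrix(0, nrow = length(axis), ncol = nrow(bands))
  for (j in seq_len(nrow(bands))) {
    d <- axis - bands$center[j]
    s <- bands$sigma[j]
    g <- exp(-d^2 / (2 * s^2))
    if (bands$mix[j] > 0) {
      gam <- s * sqrt(2 * log(2))
      l <- gam^2 / (d^2 + gam^2)
      out[, j] <- (1 - bands$mix[j]) * g + bands$mix[j] * l
    } else {
      out[, j] <- g
    }
  }
  colnames(out) <- bands$name
  out
}

# Closed-form integral of a unit-amplitude pseudo-Voigt over [lo, hi].
band_window_mass <- function(center, sigma, mix, lo, hi) {
  g <- sigma * sqrt(2 * pi) * (stats::pnorm(hi, center, sigma) -
                               stats::pnorm(lo, center, sigma))
  if (mix <= 0) return(g)
  gam <- sigma * sqrt(2 * log(2))
  l <- pi * gam * (stats::pcauchy(hi, center, gam) -
                   stats::pcauchy(lo, center, gam))
  (1 - mix) * g + mix * l
}

#' Define an age-response profile
#'
#' Band amplitudes are modulated by bounded logistic functions of donor age,
#' the simplest shape compatible with the rapid compositional change during
#' skeletal maturation followed by a plateau in adulthood. A
#' `"double_logistic"` response (sum of a falling and a rising logistic term)
#' produces the dip-then-rise trajectory seen in collagen-maturity sub-bands,
#' where the specific collagen of infant bone inflates the mature-crosslink
#' signal before enzymatic maturation takes over.
#'
#' @param direction `"increasing"` or `"decreasing"` (logistic type only).
#' @param floor,ceiling Relative amplitude multipliers bounding the response
#'   (`floor < ceiling`).
#' @param midpoint Age (years) of steepest change.
#' @param steepness Logistic rate, 1/years.
#' @param type `"logistic"` or `"double_logistic"`.
#' @param down,up For `"double_logistic"`: each a list
#'   `list(a = amplitude, midpoint =, steepness =)` for the falling and rising
#'   term; the response is `base + a_down * plogis(-k1 (age - m1)) +
#'   a_up * plogis(k2 (age - m2))` with `base = floor`.
#' @return An object of class `"age_response"`.
#' @export
age_response <- function(direction = c("increasing", "decreasing"),
                         floor = 0.8, ceiling = 1.25,
                         midpoint = 18, steepness = 0.1,
                         type = c("logistic", "double_logistic"),
                         down = NULL, up = NULL) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  if (type == "logistic") {
    stopifnot(floor < ceiling, steepness > 0)
  } else {
    stopifnot(!is.null(down), !is.null(up))
  }
  structure(list(direction = direction, floor = floor, ceiling = ceiling,
                 midpoint = midpoint, steepness = steepness, type = type,
                 down = down, up = up),
            class = "age_response")
}

#' Amplitude multiplier of a band at a given age
#'
#' Logistic responses evaluate
#' `floor + (ceiling - floor) / (1 + exp(-s (age - midpoint)))` with the sign
#' of `s` set by the direction, so mineral-class bands rise with age and
#' organic bands fall, bounded by `[floor, ceiling]`.
#'
#' @param age Age in years (vectorised), `>= 0`.
#' @param response An [age_response()].
#' @return Numeric multiplier(s).
#' @export
age_amplitude <- function(age, response) {
  stopifnot(inherits(response, "age_response"), all(age >= 0))
  if (response$type == "double_logistic") {
    d <- response$down; u <- response$up
    return(response$floor +
             d$a * stats::plogis(-d$steepness * (age - d$midpoint)) +
             u$a * stats::plogis(u$steepness * (age - u$midpoint)))
  }
  s <- if (response$direction == "increasing") response$steepness else -response$steepness
  response$floor + (response$ceiling - response$floor) *
    stats::plogis(s * (age - response$midpoint))
}

#' Default age-response profiles
#'
#' One named profile per biological process, chosen so that the three
#' mineral-linked outcomes (mineral/matrix, carbonate/phosphate,
#' crystallinity) rise monotonically with age while the organic amide
#' envelope falls. Processes are given different midpoints and rates --
#' primary mineralisation saturates early (midpoint 18 y), carbonate
#' substitution and crystal perfection mature more slowly (midpoints
#' 18-30 y with gentler slopes), and collagen crosslink turnover continues
#' into later life -- so composite spectra retain age information beyond the
#' mineralisation plateau.
#'
#' @return Named list of [age_response()] objects.
#' @export
default_age_responses <- function() {
  list(
    flat = age_response("increasing", floor = 1 - 1e-9, ceiling = 1 + 1e-9,
                        midpoint = 18, steepness = 0.1),
    mineral_up = age_response("increasing", floor = 0.78, ceiling = 1.30,
                              midpoint = 18, steepness = 0.12),
    carbonate_up = age_response("increasing", floor = 0.70, ceiling = 1.45,
                                midpoint = 18, steepness = 0.12),
    crystal_up = age_response("increasing", floor = 0.70, ceiling = 1.40,
                              midpoint = 30, steepness = 0.06),
    disorder_down = age_response("decreasing", floor = 0.70, ceiling = 1.40,
                                 midpoint = 30, steepness = 0.06),
    crystal_mineral_up = age_response("increasing", floor = 0.75,
                                      ceiling = 1.60, midpoint = 20,
                                      steepness = 0.10),
    organic_down = age_response("decreasing", floor = 0.80, ceiling = 1.15,
                                midpoint = 18, steepness = 0.10),
    collagen_slow_down = age_response("decreasing", floor = 0.75,
                                      ceiling = 1.20, midpoint = 35,
                                      steepness = 0.05),
    pyr_dip_rise = age_response(type = "double_logistic", floor = 0.75,
                                down = list(a = 0.35, midpoint = 4,
                                            steepness = 0.5),
                                up = list(a = 0.45, midpoint = 22,
                                          steepness = 0.10)),
    dhlnl_down = age_response("decreasing", floor = 0.65, ceiling = 1.35,
                              midpoint = 12, steepness = 0.12)
  )
}

#' Default band tables for bone FTIR and Raman spectra
#'
#' Band positions follow the standard assignments for bone: the phosphate
#' nu1 nu3 envelope (900-1200 cm^-1 FTIR), carbonate nu2 (850-890 FTIR),
#' amide I/II/III, CH2 wags, and on the Raman side phosphate nu1 (930-980),
#' nu2 (410-460), nu4 (587), the carbonate nu1 / phosphate nu3 composite
#' (1050-1100), proline/hydroxyproline and phenylalanine rings. Crystallinity
#' is carried by narrow crystalline/disordered sub-bands: 1030 vs 1020 cm^-1
#' under the FTIR phosphate envelope, and a narrow + broad component pair of
#' the Raman phosphate nu1 peak whose balance sharpens the peak with age.
#' Collagen maturity is carried by mature (1660, pyridinoline) and immature
#' (1690, DHLNL) crosslink sub-bands under the amide I envelope.
#'
#' Amplitudes are in absorbance units (FTIR, scaled so healthy pixels stay
#' within the 0.3 quality ceiling in the 1475-1724 cm^-1 window) or detector
#' counts (Raman).
#'
#' @param modality `"ftir"` or `"raman"`.
#' @return A band table (data frame), one row per band.
#' @export
default_band_table <- function(modality = c("ftir", "raman")) {
  modality <- match.arg(modality)
  if (modality == "ftir") {
    rbind(
      band_spec("oh_nh_stretch", 3300, 100, "organic", 0.050, 0.5, "organic_down"),
      band_spec("ch_stretch",    2920,  30, "organic", 0.030, 0.5, "organic_down"),
      band_spec("lipid_ester",   1745,  10, "organic", 0.015, 0.5, "organic_down"),
      band_spec("amide_i",       1652,  25, "organic", 0.120, 0.5, "organic_down"),
      band_spec("pyr_1660",      1660,   8, "organic", 0.020, 0.0, "pyr_dip_rise"),
      band_spec("dhlnl_1690",    1690,   8, "organic", 0.012, 0.0, "dhlnl_down"),
      band_spec("amide_ii",      1550,  28, "organic", 0.090, 0.5, "organic_down"),
      band_spec("ch2_1445",      1445,  12, "organic", 0.025, 0.5, "organic_down"),
      band_spec("ch2_1410",      1410,  12, "organic", 0.020, 0.5, "organic_down"),
      band_spec("amide_iii",     1240,  35, "organic", 0.050, 0.5, "collagen_slow_down"),
      band_spec("po4_v1v3",      1035,  48, "mineral", 0.320, 0.0, "mineral_up"),
      band_spec("po4_cryst_1030", 1030,  8, "mineral", 0.020, 0.0, "crystal_up"),
      band_spec("po4_disord_1020", 1020, 8, "mineral", 0.020, 0.0, "disorder_down"),
      band_spec("co3_v2",         870,  10, "carbonate", 0.015, 0.0, "carbonate_up")
    )
  } else {
    rbind(
      band_spec("po4_v2",        435, 14, "mineral", 200, 0.5, "mineral_up"),
      band_spec("po4_v4",        587, 12, "mineral", 150, 0.5, "mineral_up"),
      band_spec("hydroxyproline", 874,  9, "organic", 120, 0.5, "organic_down"),
      band_spec("proline",        920,  9, "organic", 110, 0.5, "organic_down"),
      band_spec("po4_v1_narrow",  958,  6.5, "mineral", 600, 0.0, "crystal_mineral_up"),
      band_spec("po4_v1_broad",   958, 11,   "mineral", 500, 0.0, "disorder_down"),
      band_spec("phenylalanine", 1003,  5, "organic",  90, 0.5, "organic_down"),
      band_spec("co3_v1_po4_v3", 1072, 12, "carbonate", 100, 0.0, "carbonate_up"),
      band_spec("amide_iii",     1255, 30, "organic", 140, 0.5, "organic_down"),
      band_spec("ch2_1446",      1446, 14, "organic", 160, 0.5, "organic_down"),
      band_spec("amide_i",       1668, 28, "organic", 200, 0.5, "collagen_slow_down"),
      band_spec("pyr_1660",      1660,  8, "organic",  40, 0.0, "pyr_dip_rise"),
      band_spec("dhlnl_1690",    1690,  8, "organic",  25, 0.0, "dhlnl_down")
    )
  }
}

# Validate a band table against a modality axis; centers must lie inside.
validate_bands <- function(bands, axis) {
  needed <- c("name", "center", "sigma", "class", "amplitude", "mix", "response")
  if (!all(needed %in% names(bands))) {
    stop("band table lacks columns: ",
         paste(setdiff(needed, names(bands)), collapse = ", "))
  }
  out_of_axis <- bands$center < min(axis) | bands$center > max(axis)
  if (any(out_of_axis)) {
    stop("band center(s) outside the axis range: ",
         paste(bands$name[out_of_axis], collapse = ", "))
  }
  if (any(bands$sigma <= 0)) stop("band sigma must be > 0")
  if (any(bands$mix < 0 | bands$mix > 1)) stop("mix fraction must be in [0, 1]")
  invisible(bands)
}

# Band amplitudes at a given age: base amplitude x age response.
band_amplitudes_at_age <- function(bands, age, responses = default_age_responses()) {
  mult <- vapply(bands$response, function(r) {
    if (!r %in% names(responses)) stop("unknown age response: ", r)
    age_amplitude(age, responses[[r]])
  }, numeric(1))
  bands$amplitude * mult
}
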