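#' Age-stage definitions
#'
#' The six developmental stages used for group comparisons: infants (0-3 y),
#' children (3-12), adolescents (12-19), early adults (19-35), mid-adults
#' (35-60) and elderly adults (>60). Intervals are left-closed/right-open,
#' with the final stage open-ended, so every non-negative age maps to exactly
#' one stage.
#'
#' @return Data frame with columns `label`, `lo`, `hi` (`hi = Inf` for the
#'   last stage).
#' @export
age_stages <- function() {
  data.frame(
    label = c("0-3", "3-12", "12-19", "19-35", "35-60", ">60"),
    lo = c(0, 3, 12, 19, 35, 60),
    hi = c(3, 12, 19, 35, 60, Inf),
    stringsAsFactors = FALSE
  )
}

# Reference stage proportions of the study design (n = 40:
# 8 infants, 2 children, 3 adolescents, 5 early adults, 17 mid-adults,
# 5 elderly).
reference_stage_counts <- function() c(8L, 2L, 3L, 5L, 17L, 5L)

# Largest-remainder apportionment of n donors over the six stages, following
# the reference proportions; when n >= 6 every stage is guaranteed at least
# one donor (shortfalls are taken from the largest stages).
stage_allocation <- function(n_donors) {
  ref <- reference_stage_counts()
  p <- ref / sum(ref)
  raw <- n_donors * p
  alloc <- floor(raw)
  rem <- raw - alloc
  short <- n_donors - sum(alloc)
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    alloc[take] <- alloc[take] + 1
  }
  if (n_donors >= 6) {
    while (any(alloc == 0)) {
      give <- which(alloc == 0)[1]
      from <- which.max(alloc)
      alloc[from] <- alloc[from] - 1
      alloc[give] <- alloc[give] + 1
    }
  }
  as.integer(alloc)
}

#' Design a donor cohort
#'
#' Draws donor ages stratified over the six age stages so that the cohort
#' reproduces the sampling design of a cross-sectional bone study: with the
#' default `n_donors = 40` the stage sizes are exactly (8, 2, 3, 5, 17, 5);
#' for other sizes a largest-remainder apportionment of those proportions is
#' used, with every stage populated whenever `n_donors >= 6`. Ages within a
#' stage are drawn uniformly. Every donor is acquired at all three cranial
#' structures (lamina externa, diploe, lamina interna), with 2 FTIR FPA
#' images and 3 Raman point spectra per structure.
#'
#' @param n_donors Number of donors (>= 1; >= 6 to populate all stages).
#' @param age_min,age_max Age range in years (`age_min < age_max`).
#' @param seed RNG seed; the same seed yields an identical cohort.
#' @param stage_sizes Optional integer vector of six stage sizes overriding
#'   the apportionment (must sum to `n_donors`).
#' @return An object of class `"cohort_design"`: a list with `donors`
#'   (data frame `donor_id`, `age`, `age_stage`), `structures`,
#'   `ftir_images_per_structure` (2), `raman_spectra_per_structure` (3) and
#'   the `seed`.
#' @export
make_cohort <- function(n_donors = 40, age_min = 0, age_max = 74, seed = 1,
                        stage_sizes = NULL) {
  if (n_donors < 1) stop("invalid design: n_donors must be >= 1")
  if (age_min >= age_max) stop("age_min must be < age_max")
  stages <- age_stages()
  if (is.null(stage_sizes)) {
    stage_sizes <- if (n_donors >= 6) stage_allocation(n_donors) else {
      # too few donors to populate all stages: fill from the largest stages
      alloc <- integer(6)
      ord <- order(reference_stage_counts(), decreasing = TRUE)
      alloc[ord[seq_len(n_donors)]] <- 1L
      alloc
    }
  } else {
    stage_sizes <- as.integer(stage_sizes)
    if (length(stage_sizes) != 6 || sum(stage_sizes) != n_donors) {
      stop("stage_sizes must be six integers summing to n_donors")
    }
  }
  ages <- local_seed(seed, {
    unlist(lapply(seq_len(6), function(k) {
      n_k <- stage_sizes[k]
      if (n_k == 0) return(numeric(0))
      lo <- max(stages$lo[k], age_min)
      hi <- min(if (is.infinite(stages$hi[k])) age_max else stages$hi[k], age_max)
      if (lo >= hi) stop("age range does not cover stage ", stages$label[k])
      # keep draws strictly inside the stage so assignment is unambiguous
      stats::runif(n_k, lo, hi - 1e-6)
    }))
  })
  donors <- data.frame(
    donor_id = sprintf("D%02d", seq_len(n_donors)),
    age = round(ages, 2),
    stringsAsFactors = FALSE
  )
  donors$age_stage <- assign_age_stage(donors$age)
  structure(
    list(donors = donors,
         structures = c("lamina_externa", "diploe", "lamina_interna"),
         ftir_images_per_structure = 2L,
         raman_spectra_per_structure = 3L,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d donors, ages %.1f-%.1f y, seed %d\n",
              nrow(x$donors), min(x$donors$age), max(x$donors$age), x$seed))
  print(table(x$donors$age_stage))
  invisible(x)
}
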