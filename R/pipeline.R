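#' Simulate and preprocess the FTIR arm of a cohort
#'
#' For every (donor, structure): simulate the 2 FPA images, run the FTIR
#' preprocessing chain and keep the structure-averaged spectrum. Images are
#' generated and discarded one structure at a time, so memory stays flat.
#'
#' @param design A [make_cohort()] design.
#' @param bands,responses,noise Generator configuration.
#' @param seed Master seed (hierarchically split per donor/structure).
#' @param ... Passed to [preprocess_ftir()].
#' @return List of `3 x n_donors` averaged [spectrum()]s (donor-major,
#'   structure-minor order); attribute `"quality_counts"` is a data frame of
#'   kept/removed pixel counts per (donor, structure).
#' @export
cohort_ftir_averages <- function(design, bands = default_band_table("ftir"),
                                 responses = default_age_responses(),
                                 noise = noise_model("ftir"), seed = 1, ...) {
  out <- vector("list", nrow(design$donors) * length(design$structures))
  qc <- list()
  k <- 0
  for (i in seq_len(nrow(design$donors))) {
    for (st in design$structures) {
      imgs <- simulate_ftir_structure(design, i, st, bands, responses,
                                      noise, seed)
      avg <- preprocess_ftir(imgs, ...)
      k <- k + 1
      out[[k]] <- avg
      reps <- attr(avg, "quality")
      qc[[k]] <- data.frame(
        donor_id = design$donors$donor_id[i], structure = st,
        n_kept = sum(vapply(reps, `[[`, integer(1), "n_kept")),
        n_removed = sum(vapply(reps, `[[`, integer(1), "n_removed")),
        stringsAsFactors = FALSE)
    }
  }
  attr(out, "quality_counts") <- do.call(rbind, qc)
  out
}

#' Simulate and preprocess the Raman arm of a cohort
#'
#' @param design A [make_cohort()] design.
#' @param bands,responses,noise Generator configuration.
#' @param seed Master seed.
#' @param ... Passed to [preprocess_raman()].
#' @return List of `3 x n_donors` averaged [spectrum()]s (donor-major,
#'   structure-minor order).
#' @export
cohort_raman_averages <- function(design, bands = default_band_table("raman"),
                                  responses = default_age_responses(),
                                  noise = noise_model("raman"), seed = 1, ...) {
  spectra <- simulate_raman_cohort(design, bands, responses, noise, seed)
  keys <- vapply(spectra, function(s) paste(s$donor_id, s$structure, sep = "|"),
                 character(1))
  order_keys <- unique(keys)             # donor-major, structure-minor
  lapply(order_keys, function(k) {
    preprocess_raman(spectra[keys == k], ...)
  })
}
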