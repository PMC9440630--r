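#!/usr/bin/env Rscript
# Stage 6: chronological-age regression. Kennard-Stone 70/30 split,
# venetian-blind 20-fold CV for the latent-variable count, PLS on the full
# spectral range and GA-PLS on the GA-selected windows, for the 8-outcome
# panel and both spectral arms. Emits a per-model summary table.
#
# GA here runs at reduced scale (population 20, <= 25 generations, 5
# replicate runs, window width 5 FTIR / 24 Raman channels) so the whole
# stage completes in a few minutes on one core; frequencies are coarser
# than a 50-replicate run but the selected regions are stable.

suppressMessages(library(osteospectra))

seed <- 1
favg <- read_spectra("results/ftir_averaged")
ravg <- read_spectra("results/raman_averaged")
dm_f <- assemble_data_matrix(favg)
dm_r <- assemble_data_matrix(ravg)

rows <- list()

# 8-outcome panel model (both modalities' four ratios per sample)
fo <- cohort_outcomes(favg); ro <- cohort_outcomes(ravg)
stopifnot(all(fo$donor_id == ro$donor_id & fo$structure == ro$structure))
X8 <- as.matrix(cbind(fo[, 5:8], ro[, 5:8]))
colnames(X8) <- c(paste0("ftir_", names(fo)[5:8]),
                  paste0("raman_", names(ro)[5:8]))
m8 <- build_age_model(X8, fo$age, use_ga = FALSE)
rows[["eight_outcomes_pls"]] <- cbind(instrument = "eight outcomes",
                                      m8$summary)
v8 <- vip_scores(m8$model)
cat("8-outcome model: top VIP =", colnames(X8)[which.max(v8)], "\n")

run_arm <- function(dm, label, width) {
  pls <- build_age_model(dm$X, dm$y, use_ga = FALSE)
  cfg <- ga_config(population = 20, window_width = width,
                   max_generations = 25, replicate_runs = 5, lv_cap = 8,
                   early_stop = 10)
  ga <- build_age_model(dm$X, dm$y, use_ga = TRUE, cfg = cfg,
                        seed = derive_seed(seed, 6L),
                        variable_labels = dm$wavenumber)
  sel <- data.frame(wavenumber = ga$selected_labels)
  write.csv(sel, sprintf("results/ga_selected_%s.csv", label),
            row.names = FALSE)
  freq <- data.frame(
    window = seq_along(ga$ga$frequency),
    start_wavenumber = dm$wavenumber[vapply(ga$ga$windows, `[`, numeric(1), 1)],
    frequency = ga$ga$frequency)
  write.csv(freq, sprintf("results/ga_frequency_%s.csv", label),
            row.names = FALSE)
  list(pls = cbind(instrument = label, pls$summary),
       ga = cbind(instrument = label, ga$summary))
}

f <- run_arm(dm_f, "ftir", width = 5)
rows[["ftir_pls"]] <- f$pls; rows[["ftir_ga"]] <- f$ga
r <- run_arm(dm_r, "raman", width = 24)
rows[["raman_pls"]] <- r$pls; rows[["raman_ga"]] <- r$ga

model_tab <- do.call(rbind, rows)
write.csv(model_tab, "results/age_models.csv", row.names = FALSE)
cat("\nAge-estimation model summary:\n")
print(model_tab, row.names = FALSE, digits = 4)

best <- model_tab[which.max(model_tab$r2pred), ]
cat(sprintf("\nBest model: %s %s (R2Pred %.3f, RMSEP %.3f y)\n",
            best$instrument, best$method, best$r2pred, best$rmsep))
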