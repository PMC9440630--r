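#!/usr/bin/env Rscript
# Stage 4: group comparisons. Structure effects per age stage, outcome
# trajectories over the six age stages (ANOVA + SNK, or Kruskal-Wallis +
# Mann-Whitney U when diagnostics fail), and the FTIR-Raman outcome
# correlations.

suppressMessages(library(osteospectra))

favg <- read_spectra("results/ftir_averaged")
ravg <- read_spectra("results/raman_averaged")
fo <- cohort_outcomes(favg)
ro <- cohort_outcomes(ravg)

# structure comparison inside every age stage: a structure effect would
# argue against pooling the three laminae
vars <- c("mineral_matrix", "carbonate_phosphate", "crystallinity",
          "collagen_maturity")
struct <- do.call(rbind, lapply(list(fo, ro), function(tab) {
  do.call(rbind, lapply(vars, function(v) {
    do.call(rbind, lapply(levels(tab$age_stage), function(st) {
      d <- tab[tab$age_stage == st, ]
      if (min(table(d$structure)) < 2) return(NULL)
      rep <- compare_groups(d[[v]], d$structure)
      data.frame(modality = d$modality[1], outcome = v, age_stage = st,
                 test = rep$test, p_value = rep$p_value)
    }))
  }))
}))
write.csv(struct, "results/structure_comparisons.csv", row.names = FALSE)
cat(sprintf("structure effects: %d of %d stage-level tests significant\n",
            sum(struct$p_value < 0.05), nrow(struct)))

# outcome-by-age-stage trajectories (mean +/- SD with omnibus p)
stage_tab <- rbind(cbind(modality = "ftir", stage_summary(fo)),
              cbind(modality = "raman", stage_summary(ro)))
write.csv(stage_tab, "results/stage_summary.csv", row.names = FALSE)
cat("age-stage omnibus p-values:\n")
print(stage_tab[, c("modality", "outcome", "p_value", "nonparametric")],
      row.names = FALSE)

# cross-technique agreement
pear <- pearson_outcomes(fo, ro)
write.csv(pear, "results/pearson_ftir_raman.csv", row.names = FALSE)
cat("FTIR-Raman Pearson correlations:\n")
print(pear, row.names = FALSE)
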