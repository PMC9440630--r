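#!/usr/bin/env Rscript
# Stage 5: PCA of the preprocessed spectra. PC1 separates young from mature
# donors, with opposite loading signs on the phosphate envelope and the
# amide bands; the three structures do not separate.

suppressMessages(library(osteospectra))

for (mod in c("ftir", "raman")) {
  avg <- read_spectra(file.path("results", paste0(mod, "_averaged")))
  dm <- assemble_data_matrix(avg)
  p <- fit_pca(dm$X, 2)
  cat(sprintf("%s: PC1 %.2f%%, PC2 %.2f%% of variance; |cor(PC1, age)| = %.3f\n",
              toupper(mod), 100 * p$explained[1], 100 * p$explained[2],
              abs(cor(p$scores[, 1], dm$y))))
  scores <- data.frame(sample_id = dm$sample_id, age = dm$y,
                       age_stage = assign_age_stage(dm$y),
                       structure = dm$structure,
                       pc1 = p$scores[, 1], pc2 = p$scores[, 2])
  write.csv(scores, sprintf("results/pca_scores_%s.csv", mod),
            row.names = FALSE)
  loads <- data.frame(wavenumber = dm$wavenumber,
                      pc1 = p$loadings[, 1], pc2 = p$loadings[, 2])
  write.csv(loads, sprintf("results/pca_loadings_%s.csv", mod),
            row.names = FALSE)

  po4 <- if (mod == "ftir") dm$wavenumber >= 900 & dm$wavenumber <= 1200
         else dm$wavenumber >= 930 & dm$wavenumber <= 980
  amide <- if (mod == "ftir") dm$wavenumber >= 1510 & dm$wavenumber <= 1712
           else dm$wavenumber >= 1215 & dm$wavenumber <= 1300
  cat(sprintf("  PC1 mean loading: phosphate %.4f vs amide %.4f (opposite: %s)\n",
              mean(p$loadings[po4, 1]), mean(p$loadings[amide, 1]),
              mean(p$loadings[po4, 1]) * mean(p$loadings[amide, 1]) < 0))
}
cat("Wrote results/pca_scores_*.csv and results/pca_loadings_*.csv\n")
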