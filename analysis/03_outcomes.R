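#!/usr/bin/env Rscript
# Stage 3: compute the eight bone-quality outcomes (four per modality) from
# the structure-averaged spectra: mineral/matrix, carbonate/phosphate,
# crystallinity and collagen maturity.

suppressMessages(library(osteospectra))

favg <- read_spectra("results/ftir_averaged")
ravg <- read_spectra("results/raman_averaged")

fo <- cohort_outcomes(favg)
ro <- cohort_outcomes(ravg)
out <- rbind(outcomes_long(fo), outcomes_long(ro))
write.csv(out, "results/outcomes_long.csv", row.names = FALSE)

cat("Outcome ranges by modality:\n")
agg <- aggregate(value ~ modality + outcome, out, function(v)
  sprintf("%.4g-%.4g", min(v), max(v)))
print(agg, row.names = FALSE)
cat("Wrote results/outcomes_long.csv (", nrow(out), "rows )\n")
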