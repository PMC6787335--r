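#!/usr/bin/env Rscript
# Sensitivity of the retained-rule count to the standardised-lift
# threshold, per sex stratum.

library(comorbnet)

out_dir <- "results/analysis"
cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
cuts <- seq(0, 0.9, by = 0.1)

for (s in cohort_strata(cohort)) {
  ts <- threshold_sensitivity(cohort, s, cuts)
  write.csv(ts, file.path(out_dir, paste0("sensitivity_", s, ".csv")),
            row.names = FALSE)
  cat(s, ": retained rules by threshold\n", sep = "")
  print(ts, row.names = FALSE)
}
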