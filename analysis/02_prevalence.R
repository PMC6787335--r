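#!/usr/bin/env Rscript
# Survey-weighted prevalence by sex with chi-square tests and FDR
# correction, plus the morbidity-count distribution (multimorbidity
# prevalence, median condition count).

library(comorbnet)

out_dir <- "results/analysis"
cohort <- read_cohort(file.path(out_dir, "cohort.csv"))

prev <- sex_association_tests(cohort)
write.csv(as.data.frame(prev), file.path(out_dir, "prevalence_by_sex.csv"),
          row.names = FALSE)
cat(sum(prev$significant, na.rm = TRUE), "of", nrow(prev),
    "conditions differ significantly by sex after FDR correction\n")

md <- morbidity_distribution(cohort)
write.csv(md$distribution, file.path(out_dir, "morbidity_counts.csv"),
          row.names = FALSE)
cat(sprintf("weighted multimorbidity prevalence (>= 2 conditions): %.2f%%\n",
            100 * md$multimorbid))
cat(sprintf("condition-free: %.2f%%; median count: %d; max count: %d\n",
            100 * md$prop_zero, md$median_count, md$max_count))
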