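#!/usr/bin/env Rscript
# Fit the control covariate regression (volume ~ age + sex + TIV + field
# strength, noncarriers only) and propagate it to every subject-visit as
# sign-flipped z-scores that increase with atrophy.
#
# Inputs:  results/cohort.csv
# Outputs: results/control_model.json, results/zscores.csv

library(sustainz)

cohort <- read_cohort("results/cohort.csv")
cm <- fit_control_model(cohort)
write_control_model(cm, "results/control_model.json")

zm <- zscore(cohort, cm)
write.csv(cbind(zm$meta, as.data.frame(zm$z)), "results/zscores.csv",
          row.names = FALSE)

s <- control_z_summary(zm, cm)
cat(sprintf("fitted %d regions on %d controls\n", nrow(s), cm$n))
cat(sprintf("control z-scores: max |mean| = %.2e, max |SD - 1| = %.2e\n",
            max(abs(s$mean)), max(abs(s$sd - 1))))
carrier <- zm$meta$group == "carrier" & zm$meta$symptomatic == 1
cat(sprintf("median z-score, symptomatic carriers vs controls: %.2f vs %.2f\n",
            median(zm$z[carrier, ]),
            median(zm$z[zm$meta$group == "noncarrier", ])))
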