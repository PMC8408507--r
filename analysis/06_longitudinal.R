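#!/usr/bin/env Rscript
# Longitudinal consistency: label transitions of every follow-up visit
# against baseline under the baseline-fitted model, and stage progression.
#
# Inputs:  results/assignments.csv
# Outputs: results/longitudinal_transitions.csv,
#          results/longitudinal_stage_pairs.csv,
#          results/figures/stage_progression.png

library(sustainz)

asg <- read.csv("results/assignments.csv", stringsAsFactors = FALSE)
rep <- consistency(asg)
print(rep)

write.csv(data.frame(transition = names(rep$transitions),
                     count = as.integer(rep$transitions)),
          "results/longitudinal_transitions.csv", row.names = FALSE)
write.csv(rep$stage_pairs, "results/longitudinal_stage_pairs.csv",
          row.names = FALSE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
ggplot2::ggsave("results/figures/stage_progression.png",
                plot_stage_progression(rep), width = 5, height = 4,
                dpi = 120)
cat(sprintf("stage nondecreasing at %.0f%% of follow-ups\n",
            100 * rep$frac_stage_nondecreasing))
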