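#!/usr/bin/env Rscript
# The statistical comparison layer on the assigned cohort: demographics
# across the normal-appearing group and the two subtypes, mutation-subtype
# association, stage-adjusted score models with Bonferroni thresholds,
# stage-EYO correlation, and rank comparisons of symptomatic carriers
# against noncarrier relatives.
#
# Inputs:  results/cohort.csv, results/assignments.csv, results/scores.csv
# Outputs: results/stats_*.csv

library(sustainz)

cohort <- read_cohort("results/cohort.csv")
asg <- read.csv("results/assignments.csv", stringsAsFactors = FALSE)
scores <- read.csv("results/scores.csv", stringsAsFactors = FALSE)
base <- asg[asg$visit == 1, ]

demo <- do.call(rbind, lapply(c("age", "eyo", "sex"), function(v) {
  compare_groups(base, v, "label")
}))
write.csv(demo, "results/stats_demographics.csv", row.names = FALSE)
cat("demographic contrasts with p < 0.05:\n")
print(demo[demo$sig_nominal, c("variable", "group1", "group2", "p")],
      row.names = FALSE)

assoc <- mutation_subtype_association(base)
write.csv(assoc, "results/stats_mutation_association.csv", row.names = FALSE)
cat("\nmutation vs subtype (subtypable carriers only):\n")
print(assoc[, c("group1", "statistic", "p", "n1", "note")], row.names = FALSE)

corr <- stage_eyo_correlation(base)
write.csv(corr, "results/stats_stage_eyo.csv", row.names = FALSE)
cat("\nstage-EYO correlation:\n")
print(corr, row.names = FALSE)

sm <- score_model(scores, base)
write.csv(sm, "results/stats_score_models.csv", row.names = FALSE)
bon <- attr(sm, "bonferroni")
cat(sprintf("\nscore models over %d scores; Bonferroni threshold %.4g (%g)\n",
            bon["m"], bon["raw"], bon["rounded"]))
sig <- sm[sm$sig_nominal & sm$term %in%
            c("stage", grep("subtype", sm$term, value = TRUE)), ]
print(sig[, c("score", "term", "estimate", "p", "sig_bonferroni")],
      row.names = FALSE)

score_cols <- setdiff(names(scores), c("subject_id", "visit"))
sym <- merge(base[base$symptomatic == 1 & base$label != "normal_appearing",
                  c("subject_id", "visit", "label")],
             scores, by = c("subject_id", "visit"))
rel <- merge(cohort[cohort$group == "noncarrier" & cohort$relative,
                    c("subject_id", "visit")],
             scores, by = c("subject_id", "visit"))
rc <- do.call(rbind, unlist(lapply(score_cols, function(scn) {
  lapply(sort(unique(sym$label)), function(l) {
    rank_compare(sym[[scn]][sym$label == l], rel[[scn]],
                 group1 = paste0("symptomatic_", l),
                 group2 = "noncarrier_relatives", variable = scn,
                 bonferroni_m = length(score_cols))
  })
}), recursive = FALSE))
write.csv(rc, "results/stats_rank_comparisons.csv", row.names = FALSE)
cat(sprintf("\n%d of %d rank comparisons significant at 0.05\n",
            sum(rc$sig_nominal), nrow(rc)))
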