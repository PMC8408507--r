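#!/usr/bin/env Rscript
# Assign every carrier visit to normal-appearing / subtype + expected stage
# using the baseline-fitted model, and compare with the generator's truth.
#
# Inputs:  results/zscores.csv, results/model.json (refit from zscores for
#          the in-memory model), results/ground_truth.csv
# Outputs: results/assignments.csv

library(sustainz)

seed <- 42L
z <- read.csv("results/zscores.csv", stringsAsFactors = FALSE)
truth <- read.csv("results/ground_truth.csv", stringsAsFactors = FALSE)
regions <- default_model_regions()
events <- zscore_events(regions)
keep <- z$group == "carrier" & z$visit == 1
model <- fit_sustain(as.matrix(z[keep, regions]),
                     jsonlite::read_json("results/model.json")$n_subtypes,
                     events, sustain_config(seed = seed + 3L))
nms <- unlist(jsonlite::read_json("results/model.json")$subtype_names)
model <- name_subtypes(model, nms)

carrier <- z$group == "carrier"
zc <- structure(list(z = as.matrix(z[carrier, regions]),
                     meta = z[carrier, setdiff(names(z), regions)]),
                class = "zscore_matrix")
asg <- assign_cohort(zc, model)
write.csv(asg, "results/assignments.csv", row.names = FALSE)

idx <- match(paste(asg$subject_id, asg$visit),
             paste(truth$subject_id, truth$visit))
asg$true_stage <- truth$true_stage[idx]
asg$true_subtype <- truth$true_subtype[idx]
b1 <- asg$visit == 1
cat(sprintf("baseline carriers: %d normal-appearing, %s\n",
            sum(asg$label[b1] == "normal_appearing"),
            paste(names(table(asg$label[b1 & asg$label != "normal_appearing"])),
                  table(asg$label[b1 & asg$label != "normal_appearing"]),
                  sep = "=", collapse = ", ")))
cat(sprintf("true stage 0 labeled normal-appearing: %.0f%%\n",
            100 * mean(asg$label[b1 & asg$true_stage == 0] ==
                         "normal_appearing")))
hi <- b1 & asg$true_stage >= 5
cat(sprintf("true stage >= 5 assigned their true subtype: %.0f%% (n=%d)\n",
            100 * mean(asg$label[hi] == asg$true_subtype[hi]), sum(hi)))
cat(sprintf("Spearman cor(expected stage, true stage) = %.2f\n",
            cor(asg$expected_stage[b1], asg$true_stage[b1],
                method = "spearman")))
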