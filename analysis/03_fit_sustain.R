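#!/usr/bin/env Rscript
# Choose the number of progression subtypes by cross-validated information
# criterion, fit the final subtype-and-stage model on baseline carriers
# with the full greedy + MCMC budget, and write the model, its positional
# variance matrices and heatmaps.
#
# Inputs:  results/zscores.csv
# Outputs: results/cvic.csv, results/model.json,
#          results/positional_variance_<subtype>.csv,
#          results/figures/positional_variance_<subtype>.png

library(sustainz)

seed <- 42L
z <- read.csv("results/zscores.csv", stringsAsFactors = FALSE)
regions <- default_model_regions()
events <- zscore_events(regions)
keep <- z$group == "carrier" & z$visit == 1
Z <- as.matrix(z[keep, regions])

sel <- select_n_subtypes(Z, events, C_max = 3, n_folds = 10,
                         config = sustain_config(n_startpoints = 5,
                                                 split_startpoints = 2,
                                                 n_bipartitions = 3,
                                                 mcmc_iter = 0,
                                                 seed = seed + 2L))
write.csv(data.frame(C = 1:3, cvic = sel$cvic, se = sel$se),
          "results/cvic.csv", row.names = FALSE)
cat(sprintf("CVIC by C: %s (SE %s) -> chose C = %d\n",
            paste(round(sel$cvic, 1), collapse = " / "),
            paste(round(sel$se, 1), collapse = " / "), sel$chosen))

model <- fit_sustain(Z, sel$chosen, events,
                     sustain_config(seed = seed + 3L))
# name subtypes by where their early events sit (temporal vs frontal lead)
early <- sapply(model$sequences, function(s) {
  model$events$table$biomarker[s[1]]
})
nm <- ifelse(early %in% c("hippocampus", "amygdala", "temporal_pole"),
             "temporal", "frontotemporal")
if (!anyDuplicated(nm)) model <- name_subtypes(model, nm)
write_sustain_model(model, "results/model.json")
cat(sprintf("fitted %d-subtype model: fractions %s, loglik %.1f\n",
            model$C, paste(round(model$f, 2), collapse = "/"),
            model$loglik))
for (c in seq_len(model$C)) {
  cat(sprintf("subtype %s first five events: %s\n", model$subtype_names[c],
              paste(with(model$events$table,
                         paste0(biomarker, ":z", threshold))[
                           model$sequences[[c]][1:5]], collapse = ", ")))
}

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
pv <- positional_variance(model)
for (c in seq_len(model$C)) {
  nmc <- model$subtype_names[c]
  write.csv(as.data.frame(pv[[c]]),
            sprintf("results/positional_variance_%s.csv", nmc))
  ggplot2::ggsave(sprintf("results/figures/positional_variance_%s.png", nmc),
                  plot_positional_variance(pv, c),
                  width = 6, height = 4.5, dpi = 120)
}
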