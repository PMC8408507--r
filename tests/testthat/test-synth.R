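small_cfg <- function(...) {
  args <- list(n_controls = 60, n_carriers = 30, n_relatives = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

test_that("generation is byte-identical for a fixed config", {
  a <- generate_cohort(small_cfg(seed = 7))
  b <- generate_cohort(small_cfg(seed = 7))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$subjects, b$truth$subjects)
  d <- generate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$cohort, d$cohort))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_controls = -1), "nonnegative")
  expect_error(synth_config(n_symptomatic = 100), "exceeds")
  expect_error(synth_config(subtype_fractions = c(a = 0.7, b = 0.7)),
               "sum to 1")
  ev <- zscore_events(default_model_regions())
  bad <- default_true_sequences(ev)
  bad$temporal[1:2] <- bad$temporal[2:1]  # z2 before z1 for hippocampus
  expect_error(synth_config(true_sequences = bad), "valid event ordering")
})

test_that("all-stage-zero carriers are indistinguishable from controls", {
  cfg <- small_cfg(seed = 30, n_controls = 100, n_carriers = 100,
                   stage_distribution = list(p_zero = 1),
                   n_followups = 1)
  sim <- generate_cohort(cfg)
  expect_true(all(sim$truth$subjects$true_stage == 0))
  # compare after covariate correction (carriers are younger than controls
  # by design, so raw volumes differ through the nuisance effects alone)
  zm <- zscore(sim$cohort, fit_control_model(sim$cohort))
  carrier <- zm$meta$group == "carrier"
  ps <- sapply(colnames(zm$z), function(r) {
    stats::t.test(zm$z[carrier, r], zm$z[!carrier, r])$p.value
  })
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("the stratified cohort reproduces the symptomatic split exactly", {
  cfg <- synth_config(n_symptomatic = 25, seed = 3)
  sim <- generate_cohort(cfg)
  base <- sim$cohort[sim$cohort$visit == 1 & sim$cohort$group == "carrier", ]
  expect_equal(nrow(base), 82L)
  expect_equal(mean(base$symptomatic), 25 / 82)
})

test_that("noise-free carriers sit exactly on their generating trajectories", {
  cfg <- small_cfg(seed = 12)
  sim <- generate_cohort(cfg, noise_free = TRUE)
  zm <- zscore(sim$cohort, true_control_model(cfg))
  tr <- sim$truth$subjects
  g <- lapply(cfg$true_sequences, function(s) stage_means(cfg$events, s))
  for (i in which(tr$group == "carrier")) {
    want <- g[[tr$true_subtype[i]]][tr$true_stage[i] + 1L, ]
    expect_equal(unname(zm$z[i, ]), unname(want), tolerance = 1e-10)
  }
})

test_that("true stages never decrease across follow-up visits", {
  sim <- generate_cohort(small_cfg(seed = 19, n_followups = c(0.2, 0.3, 0.3, 0.2)))
  tr <- sim$truth$subjects
  for (id in unique(tr$subject_id[tr$group == "carrier"])) {
    st <- tr$true_stage[tr$subject_id == id][order(tr$visit[tr$subject_id == id])]
    expect_true(all(diff(st) >= 0))
  }
  # controls have no subtype and stage 0
  expect_true(all(is.na(tr$true_subtype[tr$group == "noncarrier"])))
  expect_true(all(tr$true_stage[tr$group == "noncarrier"] == 0L))
})

test_that("score generator recovers its own generating model by OLS", {
  cfg <- synth_config(seed = 40)
  sim <- generate_cohort(cfg)
  tr <- sim$truth$subjects

  # null case: zero offsets and slopes leave only covariates + noise
  spec0 <- list(s1 = list(intercept = 10, stage_slope = 0,
                          subtype_offsets = c(temporal = 0, frontotemporal = 0),
                          beta_age = 0, beta_sex = 0, noise_sd = 1,
                          family = "neuropsych"))
  sc0 <- generate_scores(sim$cohort, sim$truth, spec = spec0, seed = 41)
  sub <- tr$true_stage >= 1
  X <- cbind(1, as.numeric(tr$true_subtype[sub] == "frontotemporal"),
             tr$true_stage[sub])
  fit0 <- oracle_ols(X, sc0$s1[sub])
  expect_lt(abs(fit0$beta[2]), 2 * fit0$se[2])

  # stage slope -1 recovered within +/- 0.1
  spec1 <- spec0
  spec1$s1$stage_slope <- -1
  sc1 <- generate_scores(sim$cohort, sim$truth, spec = spec1, seed = 42)
  fit1 <- oracle_ols(X, sc1$s1[sub])
  expect_lt(abs(fit1$beta[3] - (-1)), 0.1)

  # memory-type scores are worse (higher) in the temporal subtype among
  # the symptomatic
  sc <- generate_scores(sim$cohort, sim$truth, seed = 43)
  key <- paste(sim$cohort$subject_id, sim$cohort$visit)
  sym <- sim$cohort$symptomatic == 1 & sim$cohort$group == "carrier"
  mt <- match(paste(sc$subject_id, sc$visit), key)
  sub_t <- tr$true_subtype[match(paste(sc$subject_id, sc$visit),
                                 paste(tr$subject_id, tr$visit))]
  sel <- sym[mt]
  med <- tapply(sc$cbi_memory[sel], sub_t[sel], median)
  expect_gt(med[["temporal"]], med[["frontotemporal"]])

  # unknown subject id
  bad <- sim$truth
  bad$subjects$subject_id[1] <- "GHOST"
  expect_error(generate_scores(sim$cohort, bad), "unknown subject")
})

test_that("the cohort CSV dialect round-trips", {
  sim <- generate_cohort(small_cfg(seed = 5))
  path <- tempfile(fileext = ".csv")
  write_cohort(sim$cohort, path)
  back <- read_cohort(path)
  expect_equal(attr(back, "regions"), attr(sim$cohort, "regions"))
  expect_equal(back$subject_id, sim$cohort$subject_id)
  expect_equal(back[[cfg_r <- attr(back, "regions")[1]]],
               sim$cohort[[cfg_r]], tolerance = 1e-12)
})
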