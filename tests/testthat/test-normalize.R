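test_that("fitting controls come out at mean 0 and SD 1 exactly", {
  sim <- generate_cohort(synth_config(seed = 50))
  cm <- fit_control_model(sim$cohort)
  zm <- zscore(sim$cohort, cm)
  s <- control_z_summary(zm, cm)
  expect_lt(max(abs(s$mean)), 1e-10)
  expect_lt(max(abs(s$sd - 1)), 1e-10)
})

test_that("null covariate design yields slopes within 2 SE of zero", {
  cfg <- synth_config(seed = 51,
                      covariate_effects = c(age = 0, tiv = 0, sex = 0,
                                            field = 0))
  sim <- generate_cohort(cfg)
  ctl <- sim$cohort[sim$cohort$group == "noncarrier", ]
  cm <- fit_control_model(sim$cohort)
  X <- cbind(1, ctl$age, as.numeric(ctl$sex == "male"), ctl$tiv,
             as.numeric(ctl$field_strength == 3))
  for (r in cfg$regions[1:3]) {
    fit <- oracle_ols(X, ctl[[r]])
    for (j in 2:5) expect_lt(abs(cm$coefficients[[r]][j]), 2 * fit$se[j])
  }
})

test_that("a known age slope is recovered and matches the OLS oracle", {
  # hippocampus base volume 7.5 ml: relative age effect -0.5/7.5 per year
  cfg <- synth_config(seed = 52,
                      covariate_effects = c(age = -0.5 / 7.5, tiv = 0.4,
                                            sex = 0.02, field = 0.01))
  sim <- generate_cohort(cfg)
  cm <- fit_control_model(sim$cohort)
  expect_lt(abs(cm$coefficients[["hippocampus"]]["age"] - (-0.5)), 0.05)
  ctl <- sim$cohort[sim$cohort$group == "noncarrier", ]
  X <- cbind(1, ctl$age, as.numeric(ctl$sex == "male"), ctl$tiv,
             as.numeric(ctl$field_strength == 3))
  fit <- oracle_ols(X, ctl$hippocampus)
  expect_equal(unname(cm$coefficients[["hippocampus"]]["age"]),
               unname(fit$beta[2]), tolerance = 1e-8)
})

test_that("z-scores implement the sign-flipped residual definition", {
  cfg <- synth_config(n_controls = 50, n_carriers = 0, seed = 53)
  sim <- generate_cohort(cfg)
  cm <- fit_control_model(sim$cohort)
  rec <- sim$cohort[1, ]
  X <- sustainz:::control_design(rec)
  for (r in cfg$regions) {
    pred <- drop(X %*% cm$coefficients[[r]][colnames(X)])
    rec[[r]] <- pred
  }
  z0 <- zscore(rec, cm)
  expect_equal(unname(z0$z[1, ]), rep(0, length(cfg$regions)))
  # one residual SD below prediction gives z = +1
  for (r in cfg$regions) rec[[r]] <- rec[[r]] - cm$sigma[[r]]
  z1 <- zscore(rec, cm)
  expect_equal(unname(z1$z[1, ]), rep(1, length(cfg$regions)))
})

test_that("z-scores are invariant to affine unit rescaling of a region", {
  sim <- generate_cohort(synth_config(n_controls = 80, n_carriers = 20,
                                      seed = 54))
  z_ml <- zscore(sim$cohort, fit_control_model(sim$cohort))
  scaled <- sim$cohort
  scaled$hippocampus <- scaled$hippocampus * 0.1  # ml -> cl, say
  z_cl <- zscore(scaled, fit_control_model(scaled))
  expect_equal(z_ml$z[, "hippocampus"], z_cl$z[, "hippocampus"],
               tolerance = 1e-9)
})

test_that("constant covariates are dropped with a warning, not a crash", {
  sim <- generate_cohort(synth_config(n_controls = 60, n_carriers = 10,
                                      seed = 55))
  sim$cohort$field_strength <- 3
  expect_warning(cm <- fit_control_model(sim$cohort), "field_3t")
  expect_equal(cm$dropped, "field_3t")
  expect_equal(unname(cm$coefficients[["hippocampus"]]["field_3t"]), 0)
  expect_s3_class(zscore(sim$cohort, cm), "zscore_matrix")
})

test_that("region set mismatches are hard errors", {
  sim <- generate_cohort(synth_config(n_controls = 60, n_carriers = 10,
                                      seed = 56))
  cm <- fit_control_model(sim$cohort)
  expect_error(zscore(sim$cohort, cm, regions = c("hippocampus", "nope")),
               "absent from model")
  cohort2 <- sim$cohort
  cohort2$hippocampus <- NULL
  expect_error(zscore(cohort2, cm), "missing from records")
})

test_that("control models survive a JSON round-trip", {
  sim <- generate_cohort(synth_config(n_controls = 60, n_carriers = 10,
                                      seed = 57))
  cm <- fit_control_model(sim$cohort)
  path <- tempfile(fileext = ".json")
  write_control_model(cm, path)
  back <- read_control_model(path)
  expect_equal(back$coefficients, cm$coefficients, tolerance = 1e-12)
  expect_equal(back$sigma, cm$sigma, tolerance = 1e-12)
  z1 <- zscore(sim$cohort, cm)
  z2 <- zscore(sim$cohort, back)
  expect_equal(z1$z, z2$z, tolerance = 1e-10)
})
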