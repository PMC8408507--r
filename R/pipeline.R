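#' Full-pipeline configuration
#'
#' Bundles every stage's settings: synthesis (or a real cohort CSV),
#' z-scoring, model selection and fitting, assignment, statistics and the
#' longitudinal check. In real-data mode (`cohort_csv` given, `synth`
#' `NULL`) synthesis is skipped and the input CSV must contain all modeled
#' region columns.
#'
#' @param out_dir output directory for the run's artifacts.
#' @param seed master seed for the run; every stochastic stage derives its
#'   stream from it.
#' @param synth a [synth_config()] (its own seed is overridden by `seed`),
#'   or `NULL` for real-data mode.
#' @param cohort_csv,scores_csv input files for real-data mode.
#' @param regions modeled regions (default: synth config's regions).
#' @param z_thresholds,z_max event grid for the progression model.
#' @param n_subtypes fixed number of subtypes, or `NULL` to choose by
#'   cross-validated information criterion.
#' @param C_max,n_folds model-selection search range and folds.
#' @param fit [sustain_config()] for the final fit (with MCMC).
#' @param cv [sustain_config()] used inside cross-validation folds
#'   (reduced budget, no MCMC).
#' @param subtype_prior assignment prior: `"fractions"` or `"flat"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 42L, synth = synth_config(),
                            cohort_csv = NULL, scores_csv = NULL,
                            regions = NULL, z_thresholds = c(1, 2, 3),
                            z_max = 5, n_subtypes = NULL, C_max = 3,
                            n_folds = 10,
                            fit = sustain_config(),
                            cv = sustain_config(n_startpoints = 5,
                                                split_startpoints = 2,
                                                n_bipartitions = 3,
                                                mcmc_iter = 0),
                            subtype_prior = "fractions") {
  if (is.null(synth) && is.null(cohort_csv)) {
    stop("either a synth config or a cohort CSV is required")
  }
  regions <- regions %||% if (!is.null(synth)) synth$regions else NULL
  structure(list(out_dir = out_dir, seed = as.integer(seed), synth = synth,
                 cohort_csv = cohort_csv, scores_csv = scores_csv,
                 regions = regions, z_thresholds = z_thresholds,
                 z_max = z_max, n_subtypes = n_subtypes, C_max = C_max,
                 n_folds = n_folds, fit = fit, cv = cv,
                 subtype_prior = subtype_prior),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `synth`, `fit`
#' and `cv` blocks are passed to [synth_config()] / [sustain_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$synth)) {
    raw$synth$covariate_effects <- unlist(raw$synth$covariate_effects) %||%
      formals(synth_config)$covariate_effects
    raw$synth$subtype_fractions <-
      unlist(raw$synth$subtype_fractions) %||%
      eval(formals(synth_config)$subtype_fractions)
    raw$synth <- do.call(synth_config, raw$synth)
  }
  for (blk in c("fit", "cv")) {
    if (!is.null(raw[[blk]])) raw[[blk]] <- do.call(sustain_config, raw[[blk]])
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, z-score it against controls, select the
#' number of subtypes by cross-validation (unless fixed), fit the final
#' model with MCMC, assign every carrier visit with the baseline-fitted
#' model, run the statistical comparison layer and the longitudinal
#' consistency check, and write all artifacts plus a machine-readable
#' manifest to `config$out_dir`. Identical seed and config produce
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return (invisibly) a list with the in-memory objects: cohort, truth,
#'   control model, z-scores, selection, model, assignments, stats,
#'   consistency report and manifest.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "figures"), showWarnings = FALSE)
  step <- function(fmt, ...) msg(paste0("[pipeline] ", fmt), ...,
                                 verbose = verbose)
  written <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, name)
    p
  }

  ## 1. cohort ---------------------------------------------------------
  truth <- NULL
  scores <- NULL
  if (!is.null(config$synth)) {
    step("simulating cohort (seed %d)", config$seed)
    sc <- config$synth
    sc$seed <- config$seed
    sim <- generate_cohort(sc)
    cohort <- sim$cohort
    truth <- sim$truth
    scores <- generate_scores(cohort, truth, seed = config$seed + 1L)
    put_csv(cohort, "cohort.csv")
    put_csv(truth$subjects, "ground_truth.csv")
    put_csv(scores, "scores.csv")
    regions <- config$regions %||% sc$regions
  } else {
    step("reading cohort from %s", config$cohort_csv)
    cohort <- read_cohort(config$cohort_csv)
    regions <- config$regions %||% attr(cohort, "regions")
    miss <- setdiff(regions, names(cohort))
    if (length(miss)) {
      stop("real-data mode: cohort lacks configured region(s): ",
           paste(miss, collapse = ", "))
    }
    if (!is.null(config$scores_csv)) {
      scores <- utils::read.csv(config$scores_csv, stringsAsFactors = FALSE)
    }
  }

  ## 2. normalization --------------------------------------------------
  step("fitting control covariate model (%d regions)", length(regions))
  cmodel <- fit_control_model(cohort, regions = regions)
  write_control_model(cmodel, file.path(out, "control_model.json"))
  written <- c(written, "control_model.json")
  zmat <- zscore(cohort, cmodel, regions = regions)
  put_csv(cbind(zmat$meta, as.data.frame(zmat$z)), "zscores.csv")

  ## 3. model selection + fit -----------------------------------------
  events <- zscore_events(regions, config$z_thresholds, config$z_max)
  carrier_base <- zmat$meta$group == "carrier" & zmat$meta$visit == 1L
  z_fit <- zmat$z[carrier_base, , drop = FALSE]
  selection <- NULL
  C <- config$n_subtypes
  if (is.null(C)) {
    step("selecting number of subtypes (C_max=%d, %d folds)",
         config$C_max, config$n_folds)
    cvcfg <- config$cv
    cvcfg$seed <- config$seed + 2L
    selection <- select_n_subtypes(z_fit, events, config$C_max,
                                   config$n_folds, cvcfg)
    C <- selection$chosen
    put_csv(data.frame(C = seq_len(config$C_max), cvic = selection$cvic,
                       se = selection$se), "cvic.csv")
    step("selected C = %d", C)
  }
  step("fitting %d-subtype model", C)
  fitcfg <- config$fit
  fitcfg$seed <- config$seed + 3L
  model <- fit_sustain(z_fit, C, events, fitcfg)
  write_sustain_model(model, file.path(out, "model.json"))
  written <- c(written, "model.json")
  figures <- character(0)
  if (!is.null(model$mcmc)) {
    pv <- positional_variance(model)
    for (c in seq_len(model$C)) {
      nm <- model$subtype_names[c]
      put_csv(as.data.frame(pv[[c]]),
              paste0("positional_variance_", nm, ".csv"))
      fig <- file.path("figures", paste0("positional_variance_", nm, ".png"))
      ggplot2::ggsave(file.path(out, fig), plot_positional_variance(pv, c),
                      width = 6, height = 4.5, dpi = 120)
      figures <- c(figures, fig)
    }
  }

  ## 4. assignment (model fitted at baseline; applied to all visits) ---
  step("assigning carrier visits")
  carrier_rows <- zmat$meta$group == "carrier"
  zcar <- structure(list(z = zmat$z[carrier_rows, , drop = FALSE],
                         meta = zmat$meta[carrier_rows, , drop = FALSE]),
                    class = "zscore_matrix")
  assignments <- assign_cohort(zcar, model,
                               subtype_prior = config$subtype_prior)
  put_csv(assignments, "assignments.csv")

  ## 5. statistics -----------------------------------------------------
  step("statistical comparison layer")
  base_assign <- assignments[assignments$visit == 1L, , drop = FALSE]
  stats_out <- list()
  demo <- do.call(rbind, lapply(c("age", "eyo", "sex"), function(v) {
    compare_groups(base_assign, v, "label")
  }))
  stats_out$demographics <- demo
  put_csv(demo, "stats_demographics.csv")
  assoc <- mutation_subtype_association(base_assign)
  stats_out$mutation_association <- assoc
  put_csv(assoc, "stats_mutation_association.csv")
  corr <- stage_eyo_correlation(base_assign)
  stats_out$stage_eyo <- corr
  put_csv(corr, "stats_stage_eyo.csv")
  if (!is.null(scores)) {
    sm <- score_model(scores, base_assign)
    stats_out$score_models <- sm
    put_csv(sm, "stats_score_models.csv")
    score_cols <- setdiff(names(scores), c("subject_id", "visit"))
    sym <- merge(base_assign[base_assign$symptomatic == 1L &
                               base_assign$label != "normal_appearing",
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
    stats_out$rank_comparisons <- rc
    put_csv(rc, "stats_rank_comparisons.csv")
  }

  ## 6. longitudinal ---------------------------------------------------
  step("longitudinal consistency")
  report <- consistency(assignments)
  put_csv(data.frame(transition = names(report$transitions),
                     count = as.integer(report$transitions)),
          "longitudinal_transitions.csv")
  put_csv(report$stage_pairs, "longitudinal_stage_pairs.csv")
  if (report$n_followups > 0L) {
    fig <- file.path("figures", "stage_progression.png")
    ggplot2::ggsave(file.path(out, fig), plot_stage_progression(report),
                    width = 5, height = 4, dpi = 120)
    figures <- c(figures, fig)
  }

  ## 7. manifest -------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("sustainz")),
    n_subtypes = C,
    outputs = lapply(stats::setNames(written, written), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out, f))))
    }),
    figures = figures,
    config = config_echo(config)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  step("done: %d output files in %s", length(written) + 1L, out)
  invisible(list(cohort = cohort, truth = truth, scores = scores,
                 control_model = cmodel, zscores = zmat,
                 selection = selection, model = model,
                 assignments = assignments, stats = stats_out,
                 consistency = report, manifest = manifest))
}

# Flat, JSON-friendly echo of the run configuration.
config_echo <- function(config) {
  list(seed = config$seed,
       mode = if (is.null(config$synth)) "real_data" else "synthetic",
       regions = config$regions,
       z_thresholds = config$z_thresholds, z_max = config$z_max,
       n_subtypes = config$n_subtypes, C_max = config$C_max,
       n_folds = config$n_folds,
       fit = unclass(config$fit), cv = unclass(config$cv),
       synth = if (!is.null(config$synth)) {
         s <- config$synth
         list(n_controls = s$n_controls, n_carriers = s$n_carriers,
              n_symptomatic = s$n_symptomatic,
              subtype_fractions = as.list(s$subtype_fractions),
              noise_sd = s$noise_sd,
              stage_increment_rate = s$stage_increment_rate)
       })
}

#' Serialize a fitted model to JSON
#'
#' Sequences are written as ordered event lists (`biomarker`, `threshold`),
#' with subtype fractions, sigma, log-likelihood and the fit configuration.
#'
#' @param model a `sustain_model`.
#' @param path output path.
#' @export
write_sustain_model <- function(model, path) {
  ev <- model$events$table
  seq_list <- lapply(seq_len(model$C), function(c) {
    s <- model$sequences[[c]]
    lapply(s, function(e) list(biomarker = ev$biomarker[e],
                               threshold = ev$threshold[e]))
  })
  names(seq_list) <- model$subtype_names
  jsonlite::write_json(list(
    n_subtypes = model$C,
    subtype_names = model$subtype_names,
    fractions = as.list(stats::setNames(model$f, model$subtype_names)),
    sigma = model$sigma,
    loglik = model$loglik,
    sequences = seq_list,
    z_max = as.list(stats::setNames(model$events$z_max,
                                    model$events$biomarkers)),
    config = unclass(model$config)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
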