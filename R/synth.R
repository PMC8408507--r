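#' Configuration of the synthetic cohort generator
#'
#' Builds the generator settings for a synthetic genetic-FTD-like cohort:
#' noncarrier controls plus mutation carriers who progress along one of a
#' small number of latent subtype-specific event orderings. Defaults mirror
#' the cohort shape the analysis is designed for: 300 noncarriers (48 of
#' them first-degree relatives used for clinical comparisons) and 82
#' carriers of whom 25 are symptomatic (late-stage) and 57 presymptomatic,
#' two latent subtypes — a temporal-led ordering and a frontal+temporal-led
#' ordering in roughly 2:1 proportion — annual follow-up scans for a subset
#' of carriers, and nuisance covariate effects (age, sex, head size,
#' scanner field strength) on the raw volumes.
#'
#' @param n_controls,n_carriers cohort sizes.
#' @param n_symptomatic `NULL` (default) draws every carrier's stage from
#'   the point-mass-at-0 + uniform-over-1..E mixture and derives the
#'   symptomatic flag from the stage; an integer forces exactly that many
#'   carriers into the late (symptomatic) stage range, with the remaining
#'   presymptomatic carriers at stage 0 or an early stage — the
#'   stratified shape of the emulated cohort (25 symptomatic / 57
#'   presymptomatic of whom 48 look normal).
#' @param n_relatives controls flagged as first-degree relatives (the
#'   clinical comparison control group).
#' @param regions modeled region names (must have rows in [region_table()]
#'   unless `region_params` supplies base volume and residual SD).
#' @param subtype_fractions named probabilities of the latent subtypes.
#' @param true_sequences named list (same names) of generating event
#'   orderings; `NULL` uses [default_true_sequences()] for the default
#'   region set.
#' @param z_thresholds,z_max event thresholds per biomarker (see
#'   [zscore_events()]).
#' @param noise_sd total residual SD on the z-score scale (stable
#'   between-subject anatomical variation plus scan-level error).
#' @param rescan_noise_sd the portion of `noise_sd` that is redrawn at
#'   every visit (scan/segmentation error); the remainder,
#'   `sqrt(noise_sd^2 - rescan_noise_sd^2)`, is a per-subject anatomical
#'   offset held fixed across visits. Cross-sectional z-scores are
#'   unaffected by the split; longitudinal stability depends on it.
#' @param covariate_effects named vector `c(age, tiv, sex, field)` of
#'   relative effect sizes: age slope per year as a fraction of the
#'   region's base volume, TIV scaling fraction, male offset fraction and
#'   3T-scanner offset fraction. Zeros give a null covariate design.
#' @param stage_distribution list with `p_zero` (probability a carrier is
#'   at stage 0 in the default mixture mode), `p_zero_presym` (probability
#'   a presymptomatic carrier is at stage 0 in stratified mode) and
#'   `symptomatic_min_stage` (lowest symptomatic stage;
#'   `NULL` = `floor(E/2) + 1`).
#' @param n_followups probability vector over 0, 1, 2, ... annual follow-up
#'   scans per carrier.
#' @param stage_increment_rate expected stages gained per year at follow-up
#'   (Poisson increments).
#' @param mutation_map named list (per subtype) of mutation-label
#'   probability vectors.
#' @param include_cerebellum also generate a cerebellar volume column
#'   (covariates + noise only; not modeled).
#' @param region_params optional data.frame `region`, `base_volume_ml`,
#'   `residual_sd_ml` overriding the atlas lookup.
#' @param seed integer seed; generation is deterministic given the config.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_controls = 300, n_carriers = 82,
                         n_symptomatic = NULL, n_relatives = 48,
                         regions = default_model_regions(),
                         subtype_fractions = c(temporal = 23 / 34,
                                               frontotemporal = 11 / 34),
                         true_sequences = NULL,
                         z_thresholds = c(1, 2, 3), z_max = 5,
                         noise_sd = 1, rescan_noise_sd = 0.25,
                         covariate_effects = c(age = -0.004, tiv = 0.40,
                                               sex = 0.02, field = 0.01),
                         stage_distribution = list(
                           p_zero = 48 / 82,
                           p_zero_presym = 48 / 57,
                           symptomatic_min_stage = NULL),
                         n_followups = c(0.39, 0.25, 0.20, 0.16),
                         stage_increment_rate = 0.3,
                         mutation_map = NULL,
                         include_cerebellum = FALSE,
                         region_params = NULL,
                         seed = 1L) {
  if (n_controls < 0 || n_carriers < 0 || (n_symptomatic %||% 0) < 0) {
    stop("counts must be nonnegative")
  }
  if ((n_symptomatic %||% 0) > n_carriers) {
    stop("n_symptomatic exceeds n_carriers")
  }
  if (n_relatives > n_controls) stop("n_relatives exceeds n_controls")
  if (abs(sum(subtype_fractions) - 1) > 1e-8) {
    stop("subtype_fractions must sum to 1")
  }
  if (is.null(names(subtype_fractions))) {
    names(subtype_fractions) <- paste0("subtype", seq_along(subtype_fractions))
  }
  events <- zscore_events(regions, z_thresholds, z_max)
  if (is.null(true_sequences)) {
    if (!identical(sort(regions), sort(default_model_regions())) ||
        length(subtype_fractions) != 2L) {
      stop("true_sequences must be given for non-default regions/subtypes")
    }
    true_sequences <- default_true_sequences(events)
    names(true_sequences) <- names(subtype_fractions)
  }
  if (!identical(sort(names(true_sequences)),
                 sort(names(subtype_fractions)))) {
    stop("true_sequences names must match subtype_fractions names")
  }
  for (nm in names(true_sequences)) {
    if (!is_valid_sequence(events, true_sequences[[nm]])) {
      stop("true_sequences[['", nm, "']] is not a valid event ordering ",
           "(must be a permutation of all events with thresholds ascending ",
           "within each biomarker)")
    }
  }
  if (is.null(mutation_map)) {
    mutation_map <- default_mutation_map(names(subtype_fractions))
  }
  sd_ <- stage_distribution
  sd_$p_zero <- sd_$p_zero %||% (48 / 82)
  sd_$p_zero_presym <- sd_$p_zero_presym %||% (48 / 57)
  sd_$symptomatic_min_stage <-
    sd_$symptomatic_min_stage %||% (floor(events$E / 2) + 1L)
  if (sd_$symptomatic_min_stage < 1 || sd_$symptomatic_min_stage > events$E) {
    stop("symptomatic_min_stage out of range")
  }
  if (rescan_noise_sd < 0 || rescan_noise_sd > noise_sd) {
    stop("rescan_noise_sd must lie in [0, noise_sd]")
  }
  structure(list(
    n_controls = n_controls, n_carriers = n_carriers,
    n_symptomatic = n_symptomatic, n_relatives = n_relatives,
    regions = regions, subtype_fractions = subtype_fractions,
    true_sequences = true_sequences, events = events,
    z_thresholds = z_thresholds, z_max = z_max, noise_sd = noise_sd,
    rescan_noise_sd = rescan_noise_sd,
    covariate_effects = covariate_effects, stage_distribution = sd_,
    n_followups = n_followups, stage_increment_rate = stage_increment_rate,
    mutation_map = mutation_map, include_cerebellum = include_cerebellum,
    region_params = region_params, seed = seed
  ), class = "synth_config")
}

#' Default generating event orderings for the two latent subtypes
#'
#' Two distinct orderings over the default six-region event set: a
#' temporal-led pattern (hippocampus, amygdala and temporal pole reach
#' their thresholds first, orbitofrontal cortex last) and a
#' frontal+temporal-led pattern (orbitofrontal cortex, anterior insula and
#' lateral temporal cortex first, medial temporal structures last). The
#' progressions are strongly staggered — each region passes all of its
#' thresholds before the next region begins — which keeps the two latent
#' orderings crisply identifiable at the modest carrier sample the default
#' cohort emulates.
#'
#' @param events the [zscore_events()] object over
#'   [default_model_regions()] with thresholds 1, 2, 3.
#' @return named list of two event-id orderings.
#' @export
default_true_sequences <- function(events) {
  stopifnot(identical(events$biomarkers, default_model_regions()))
  region_block_sequence <- function(regions) {
    unlist(lapply(regions, function(r) {
      events$events_by_bio[[match(r, events$biomarkers)]]
    }), use.names = FALSE)
  }
  list(
    temporal = region_block_sequence(c(
      "hippocampus", "amygdala", "temporal_pole",
      "lateral_temporal_cortex", "anterior_insula_cortex",
      "orbitofrontal_cortex")),
    frontotemporal = region_block_sequence(c(
      "orbitofrontal_cortex", "anterior_insula_cortex",
      "lateral_temporal_cortex", "hippocampus", "amygdala",
      "temporal_pole")))
}

default_mutation_map <- function(subtypes) {
  m <- list(
    c("IVS10+16" = 0.38, "R406W" = 0.28, "Q351R" = 0.08, "P301L" = 0.06,
      "other" = 0.20),
    c("P301L" = 0.75, "G272V" = 0.12, "L266V" = 0.13))
  stats::setNames(rep_len(m, length(subtypes)), subtypes)
}

# Region base volume / residual SD lookup with optional override.
region_params_for <- function(config) {
  atlas <- region_table(include_cerebellum = TRUE)
  if (!is.null(config$region_params)) {
    atlas <- rbind(config$region_params[, c("region", "base_volume_ml",
                                            "residual_sd_ml")],
                   atlas[!atlas$region %in% config$region_params$region,
                         c("region", "base_volume_ml", "residual_sd_ml")])
  }
  wanted <- config$regions
  if (config$include_cerebellum) wanted <- c(wanted, "cerebellum")
  miss <- setdiff(wanted, atlas$region)
  if (length(miss)) {
    stop("no volume parameters for regions: ", paste(miss, collapse = ", "),
         " (supply region_params)")
  }
  atlas[match(wanted, atlas$region), ]
}

META_COLS <- c("subject_id", "visit", "group", "mutation", "symptomatic",
               "age", "sex", "tiv", "field_strength", "eyo", "relative")

#' Generate a synthetic cohort with ground truth
#'
#' Draws covariates, latent subtypes and stages, and raw regional volumes.
#' Controls' volumes are the covariate-predicted mean plus Gaussian noise;
#' carriers' volumes are additionally reduced by `residual SD x g_b(stage)`,
#' where `g_b` is the subtype's piecewise-linear expected z-score
#' trajectory — so after control-referenced sign-flipped z-scoring a
#' carrier's expected z-score at stage k is `g_b(k)` (exactly, in
#' `noise_free` mode scored against [true_control_model()]).
#'
#' Carrier stages: `n_symptomatic` carriers are drawn uniformly from the
#' symptomatic stage range; presymptomatic carriers are at stage 0 with
#' probability `p_zero_presym`, otherwise uniform over the early stages.
#' Follow-up visits are annual, with Poisson stage increments, so true
#' stages are nondecreasing within subject.
#'
#' @param config a [synth_config()].
#' @param noise_free set all measurement noise to zero (volumes sit exactly
#'   on their expected trajectories); used by recovery tests.
#' @return list with `cohort` (one row per subject-visit; metadata columns
#'   `subject_id, visit, group, mutation, symptomatic, age, sex, tiv,
#'   field_strength, eyo, relative`, then one column per region) and
#'   `truth` (class `synth_truth`: per-visit `true_subtype`/`true_stage`,
#'   the generating sequences and the event set).
#' @export
generate_cohort <- function(config, noise_free = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    events <- config$events
    E <- events$E
    rp <- region_params_for(config)

    ## --- carriers: latent structure -----------------------------------
    nC <- config$n_carriers
    subtypes <- names(config$subtype_fractions)
    sub <- if (nC) sample(subtypes, nC, replace = TRUE,
                          prob = config$subtype_fractions) else character(0)
    s_min <- config$stage_distribution$symptomatic_min_stage
    stage <- integer(nC)
    if (is.null(config$n_symptomatic)) {
      # default: point mass at 0, otherwise uniform over 1..E
      prog <- stats::runif(nC) >= config$stage_distribution$p_zero
      if (any(prog)) stage[prog] <- sample.int(E, sum(prog), replace = TRUE)
      sympt <- stage >= s_min
    } else {
      # stratified: exactly n_symptomatic carriers in the late-stage range
      sympt <- rep(FALSE, nC)
      if (config$n_symptomatic > 0) {
        sympt[sample.int(nC, config$n_symptomatic)] <- TRUE
      }
      n_sym <- sum(sympt)
      if (n_sym) stage[sympt] <- sample(s_min:E, n_sym, replace = TRUE)
      pre <- which(!sympt)
      if (length(pre)) {
        at0 <- stats::runif(length(pre)) <
          config$stage_distribution$p_zero_presym
        n_prog <- sum(!at0)
        if (n_prog) {
          lo_max <- max(1L, s_min - 1L)
          stage[pre[!at0]] <- sample.int(lo_max, n_prog, replace = TRUE)
        }
      }
    }
    mutation <- vapply(sub, function(st) {
      mm <- config$mutation_map[[st]]
      sample(names(mm), 1L, prob = mm)
    }, character(1))

    ## --- carrier covariates -------------------------------------------
    onset_age <- stats::rnorm(nC, 53, 7)
    eyo <- -14 + 1.1 * stage + stats::rnorm(nC, 0, 6)
    age <- onset_age + eyo
    sex <- sample(c("female", "male"), nC, replace = TRUE)
    tiv <- stats::rnorm(nC, 1400, 110) + 100 * (sex == "male")
    field <- sample(c(1.5, 3), nC, replace = TRUE, prob = c(0.3, 0.7))

    ## --- control covariates -------------------------------------------
    nK <- config$n_controls
    age_k <- stats::runif(nK, 25, 70)
    sex_k <- sample(c("female", "male"), nK, replace = TRUE)
    tiv_k <- stats::rnorm(nK, 1400, 110) + 100 * (sex_k == "male")
    field_k <- sample(c(1.5, 3), nK, replace = TRUE, prob = c(0.3, 0.7))
    eyo_k <- age_k - stats::rnorm(nK, 53, 7)

    ## --- follow-up schedule (carriers only) ---------------------------
    nfu <- if (nC) sample(seq_along(config$n_followups) - 1L, nC,
                          replace = TRUE, prob = config$n_followups)
           else integer(0)

    meta <- list()
    if (nK) {
      meta[[1]] <- data.frame(
        subject_id = sprintf("CTL%03d", seq_len(nK)), visit = 1L,
        group = "noncarrier", mutation = "noncarrier", symptomatic = 0L,
        age = age_k, sex = sex_k, tiv = tiv_k, field_strength = field_k,
        eyo = eyo_k,
        relative = seq_len(nK) <= config$n_relatives,
        true_subtype = NA_character_, true_stage = 0L,
        stringsAsFactors = FALSE)
    }
    if (nC) {
      rows <- lapply(seq_len(nC), function(i) {
        vis <- 0:nfu[i]
        st <- stage[i]
        if (nfu[i] > 0) {
          inc <- stats::rpois(nfu[i], config$stage_increment_rate)
          st <- pmin(E, stage[i] + cumsum(c(0L, inc)))
        }
        data.frame(
          subject_id = sprintf("CAR%03d", i), visit = vis + 1L,
          group = "carrier", mutation = mutation[i],
          symptomatic = as.integer(sympt[i] | st >= s_min),
          age = age[i] + vis, sex = sex[i], tiv = tiv[i],
          field_strength = field[i], eyo = eyo[i] + vis,
          relative = FALSE,
          true_subtype = sub[i], true_stage = as.integer(st),
          stringsAsFactors = FALSE, row.names = NULL)
      })
      meta[[length(meta) + 1L]] <- do.call(rbind, rows)
    }
    meta <- do.call(rbind, meta)
    # symptomatic: baseline-symptomatic carriers stay labeled symptomatic;
    # presymptomatic carriers convert when their stage crosses s_min
    base_sym <- stats::ave(meta$symptomatic, meta$subject_id, FUN = cummax)
    meta$symptomatic <- as.integer(base_sym)

    ## --- raw volumes ----------------------------------------------------
    n_rows <- nrow(meta)
    subj_ids <- unique(meta$subject_id)
    n_subj <- length(subj_ids)
    subj_idx <- match(meta$subject_id, subj_ids)
    ce <- config$covariate_effects
    vol <- matrix(NA_real_, n_rows, nrow(rp),
                  dimnames = list(NULL, rp$region))
    g_by_sub <- lapply(config$true_sequences,
                       function(s) stage_means(events, s))
    for (j in seq_len(nrow(rp))) {
      base <- rp$base_volume_ml[j]
      sdj <- rp$residual_sd_ml[j]
      pred <- base +
        ce[["age"]] * base * (meta$age - 50) +
        ce[["tiv"]] * base / 1450 * (meta$tiv - 1450) +
        ce[["sex"]] * base * (meta$sex == "male") +
        ce[["field"]] * base * (meta$field_strength == 3)
      g <- numeric(n_rows)
      if (rp$region[j] %in% events$biomarkers) {
        col <- match(rp$region[j], events$biomarkers)
        isc <- meta$group == "carrier"
        if (any(isc)) {
          g[isc] <- vapply(which(isc), function(i) {
            g_by_sub[[meta$true_subtype[i]]][meta$true_stage[i] + 1L, col]
          }, numeric(1))
        }
      }
      eps <- if (noise_free) 0 else {
        # persistent anatomical offset per subject + fresh scan error
        sd_e <- config$rescan_noise_sd / config$noise_sd
        sd_u <- sqrt(1 - sd_e^2)
        sd_u * stats::rnorm(n_subj)[subj_idx] + sd_e * stats::rnorm(n_rows)
      }
      vol[, j] <- pred + sdj * (config$noise_sd * eps - g)
    }
    cohort <- cbind(meta[, META_COLS], as.data.frame(vol))
    attr(cohort, "regions") <- rp$region
    truth <- structure(list(
      subjects = meta[, c("subject_id", "visit", "group", "true_subtype",
                          "true_stage")],
      sequences = config$true_sequences,
      events = events,
      config = config
    ), class = "synth_truth")
    rownames(cohort) <- NULL
    rownames(truth$subjects) <- NULL
    list(cohort = cohort, truth = truth)
  })
}

#' The exact control regression model implied by a generator config
#'
#' Returns the covariate model (true coefficients and residual SDs) the
#' generator draws from, in the same form as [fit_control_model()] output.
#' Scoring a noise-free cohort against it reproduces the generating
#' trajectories exactly.
#'
#' @param config a [synth_config()].
#' @return a `control_model` object.
#' @export
true_control_model <- function(config) {
  rp <- region_params_for(config)
  ce <- config$covariate_effects
  coefs <- lapply(seq_len(nrow(rp)), function(j) {
    base <- rp$base_volume_ml[j]
    b_age <- ce[["age"]] * base
    b_tiv <- ce[["tiv"]] * base / 1450
    c("(Intercept)" = base - 50 * b_age - 1450 * b_tiv,
      age = b_age, sex_male = ce[["sex"]] * base, tiv = b_tiv,
      field_3t = ce[["field"]] * base)
  })
  names(coefs) <- rp$region
  structure(list(
    coefficients = coefs,
    sigma = stats::setNames(rp$residual_sd_ml * config$noise_sd, rp$region),
    covariates = c("age", "sex_male", "tiv", "field_3t"),
    dropped = character(0), n = NA_integer_, source = "generator"
  ), class = "control_model")
}

#' Default clinical / neuropsychological score generating model
#'
#' A small battery emulating the structure of the cohort's clinical layer:
#' executive measures worse in the frontotemporal subtype, memory measures
#' worse in the temporal subtype, naming and fluency driven by stage alone.
#' Offsets apply to carriers with stage >= 1 (the subtypable population the
#' fitted model describes); controls and stage-0 carriers are drawn with no
#' subtype effect.
#'
#' @param subtypes subtype names (default temporal / frontotemporal).
#' @return named list of per-score generating parameters, each with
#'   `intercept`, `stage_slope`, `subtype_offsets`, `beta_age`, `beta_sex`,
#'   `noise_sd` and `family` (`neuropsych` or `clinical`).
#' @export
default_score_spec <- function(subtypes = c("temporal", "frontotemporal")) {
  off <- function(...) {
    v <- c(...)
    out <- stats::setNames(rep(0, length(subtypes)), subtypes)
    out[names(v)] <- v
    out
  }
  list(
    digit_span_forward = list(intercept = 12, stage_slope = -0.05,
      subtype_offsets = off(frontotemporal = -3), beta_age = -0.02,
      beta_sex = 0, noise_sd = 2, family = "neuropsych"),
    block_design = list(intercept = 40, stage_slope = -0.4,
      subtype_offsets = off(frontotemporal = -8), beta_age = -0.15,
      beta_sex = 0, noise_sd = 8, family = "neuropsych"),
    boston_naming = list(intercept = 28, stage_slope = -0.5,
      subtype_offsets = off(), beta_age = -0.02, beta_sex = 0,
      noise_sd = 2, family = "neuropsych"),
    fluency_category = list(intercept = 22, stage_slope = -0.6,
      subtype_offsets = off(), beta_age = -0.05, beta_sex = 0,
      noise_sd = 4, family = "neuropsych"),
    tmt_a_time = list(intercept = 35, stage_slope = 3,
      subtype_offsets = off(frontotemporal = 20), beta_age = 0.4,
      beta_sex = 0, noise_sd = 12, family = "neuropsych"),
    cdr_memory = list(intercept = 0.2, stage_slope = 0.02,
      subtype_offsets = off(temporal = 0.8), beta_age = 0, beta_sex = 0,
      noise_sd = 0.4, family = "clinical"),
    cbi_memory = list(intercept = 2, stage_slope = 0.15,
      subtype_offsets = off(temporal = 8), beta_age = 0, beta_sex = 0,
      noise_sd = 4, family = "clinical")
  )
}

#' Generate clinical / neuropsychological scores for a cohort
#'
#' Scores are drawn from the linear model
#' `score = intercept + subtype_offset + stage_slope * stage +
#' beta_age * (age - 50) + beta_sex * male + noise`, the same structural
#' form the statistical layer fits. Subtype offsets apply to carriers at
#' stage >= 1 only; controls are drawn at stage 0 with no subtype offset.
#'
#' @param cohort cohort table from [generate_cohort()].
#' @param truth matching `synth_truth` object.
#' @param spec per-score generating parameters ([default_score_spec()]).
#' @param seed optional integer seed.
#' @return data.frame `subject_id`, `visit`, then one column per score.
#' @export
generate_scores <- function(cohort, truth, spec = NULL, seed = NULL) {
  tr <- truth$subjects
  key_c <- paste(cohort$subject_id, cohort$visit)
  key_t <- paste(tr$subject_id, tr$visit)
  if (!all(key_t %in% key_c)) {
    stop("unknown subject id in truth: ",
         paste(utils::head(setdiff(key_t, key_c)), collapse = ", "))
  }
  spec <- spec %||%
    default_score_spec(names(truth$config$subtype_fractions))
  idx <- match(key_t, key_c)
  age <- cohort$age[idx]
  male <- as.numeric(cohort$sex[idx] == "male")
  stage <- tr$true_stage
  subtyped <- !is.na(tr$true_subtype) & stage >= 1L
  with_seed(seed, {
    out <- data.frame(subject_id = tr$subject_id, visit = tr$visit,
                      stringsAsFactors = FALSE)
    for (nm in names(spec)) {
      p <- spec[[nm]]
      offset <- numeric(nrow(tr))
      if (any(subtyped)) {
        offset[subtyped] <- p$subtype_offsets[tr$true_subtype[subtyped]]
      }
      out[[nm]] <- p$intercept + offset + p$stage_slope * stage +
        p$beta_age * (age - 50) + p$beta_sex * male +
        stats::rnorm(nrow(tr), 0, p$noise_sd)
    }
    out
  })
}

#' Write / read the cohort CSV dialect
#'
#' One header row; metadata columns `subject_id, visit, group, mutation,
#' symptomatic, age, sex, tiv, field_strength, eyo, relative`, then one
#' column per region.
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `read_cohort` returns the cohort with a `regions` attribute.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(META_COLS, "relative"), names(df))
  if (length(miss)) {
    stop("cohort CSV lacks required columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(df$relative)) df$relative <- FALSE
  attr(df, "regions") <- setdiff(names(df), META_COLS)
  df
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("synthetic ground truth:", nrow(x$subjects), "subject-visits,",
      length(x$sequences), "latent subtype(s)\n")
  invisible(x)
}
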