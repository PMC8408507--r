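#' Fitting configuration for the subtype progression model
#'
#' Collects the numerical budgets of the fit. Defaults are sized for a
#' final desk-scale fit; cross-validated model selection uses a reduced
#' budget (see [select_n_subtypes()]).
#'
#' @param sigma measurement noise SD on the z-score scale (data are
#'   control-referenced z-scores, so 1 is the natural default).
#' @param n_startpoints random restarts of the greedy sequence ascent.
#' @param split_startpoints restarts used when fitting the two halves of a
#'   candidate cluster bipartition.
#' @param n_bipartitions random bipartitions tried per cluster split.
#' @param em_max_iter,em_tol expectation-maximisation stopping rule
#'   (absolute log-likelihood increase below `em_tol`).
#' @param mcmc_iter,mcmc_burn,mcmc_thin Markov chain Monte Carlo budget for
#'   sequence uncertainty; `mcmc_iter = 0` skips MCMC entirely.
#' @param min_cluster smallest cluster size eligible for splitting.
#' @param seed integer seed making the whole fit reproducible; `NULL` uses
#'   (and advances) the caller's RNG stream.
#' @return list of class `sustain_config`.
#' @export
sustain_config <- function(sigma = 1, n_startpoints = 25,
                           split_startpoints = 3, n_bipartitions = 10,
                           em_max_iter = 100, em_tol = 1e-4,
                           mcmc_iter = 10000, mcmc_burn = 1000,
                           mcmc_thin = 10, min_cluster = 4, seed = NULL) {
  structure(list(sigma = sigma, n_startpoints = n_startpoints,
                 split_startpoints = split_startpoints,
                 n_bipartitions = n_bipartitions,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 mcmc_iter = mcmc_iter, mcmc_burn = mcmc_burn,
                 mcmc_thin = mcmc_thin, min_cluster = min_cluster,
                 seed = seed),
            class = "sustain_config")
}

# Valid insertion slots for event e once removed from the sequence: after its
# lower-threshold sibling and before its higher-threshold sibling.
insertion_slots <- function(events, others, e) {
  sibs <- events$events_by_bio[[events$bio_idx[e]]]
  r <- match(e, sibs)
  lo <- if (r > 1L) match(sibs[r - 1L], others) else 0L
  hi <- if (r < length(sibs)) match(sibs[r + 1L], others) else length(others) + 1L
  seq.int(lo + 1L, hi)
}

# One greedy ascent from sequence s: repeatedly relocate single events to
# their best position until no move improves the (weighted) log-likelihood.
# The move loop lives in compiled code (src/seq_loglik.cpp) and draws its
# per-pass event order from R's RNG, so fits are reproducible under a seed.
greedy_ascent <- function(Z, events, s, sigma, weights, zsq = NULL,
                          max_passes = 50L) {
  cpp_greedy_ascent(as.integer(s), Z, sigma, events$bio_start,
                    events$threshold, events$z_max, weights,
                    as.integer(max_passes))
}

#' Fit a single event sequence by greedy ascent with random restarts
#'
#' Maximises the stage-marginalised log-likelihood of one progression
#' pattern over event orderings, using single-event relocation moves from
#' multiple random starting permutations. The returned ordering is a local
#' maximum under relocation moves; restarts make global recovery reliable
#' on well-separated data.
#'
#' @param Z numeric matrix of sign-flipped z-scores (subjects x biomarkers,
#'   columns ordered as `events$biomarkers`).
#' @param events a [zscore_events()] object.
#' @param init optional starting sequence (used as the first start point).
#' @param weights optional per-subject nonnegative weights (used as
#'   responsibilities by the mixture fit).
#' @param sigma measurement noise SD.
#' @param n_startpoints number of greedy restarts.
#' @param seed optional integer seed.
#' @return list with `sequence` (integer event ids) and `loglik`.
#' @export
fit_sequence <- function(Z, events, init = NULL, weights = NULL, sigma = 1,
                         n_startpoints = 25, seed = NULL) {
  Z <- as_z_matrix(Z, events)
  if (nrow(Z) < 1L) stop("empty cluster: at least one subject is required")
  if (!is.null(init) && !is_valid_sequence(events, init)) {
    stop("init is not a valid event sequence")
  }
  zsq <- rowSums(Z * Z)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(max(1L, n_startpoints))) {
      s0 <- if (i == 1L && !is.null(init)) init else random_sequence(events)
      fit <- greedy_ascent(Z, events, s0, sigma, weights, zsq)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best
  })
}

# Responsibility matrix and total mixture log-likelihood.
e_step <- function(Z, events, sequences, f, sigma, zsq = NULL) {
  ml <- vapply(sequences, function(s) {
    seq_margll(events, s, Z, sigma)
  }, numeric(nrow(Z)))
  lw <- sweep(ml, 2L, log(f), "+")
  li <- row_logsumexp(lw)
  list(resp = exp(lw - li), loglik = sum(li), margll = ml)
}

# Alternate soft assignment and per-subtype sequence refits until the total
# log-likelihood stabilises. Warm-started single-restart M-steps keep the
# ascent monotone.
em_fit <- function(Z, events, sequences, f, config, zsq = NULL) {
  zsq <- zsq %||% rowSums(Z * Z)
  trace <- numeric(0)
  es <- e_step(Z, events, sequences, f, config$sigma, zsq)
  for (it in seq_len(config$em_max_iter)) {
    trace <- c(trace, es$loglik)
    f_new <- colMeans(es$resp)
    f_new <- pmax(f_new, 1e-12)
    f_new <- f_new / sum(f_new)
    sequences <- lapply(seq_along(sequences), function(c) {
      fit_sequence(Z, events, init = sequences[[c]],
                   weights = es$resp[, c], sigma = config$sigma,
                   n_startpoints = 1)$sequence
    })
    f <- f_new
    es_new <- e_step(Z, events, sequences, f, config$sigma, zsq)
    if (es_new$loglik - es$loglik < config$em_tol) {
      es <- es_new
      break
    }
    es <- es_new
  }
  trace <- c(trace, es$loglik)
  list(sequences = sequences, f = f, loglik = es$loglik, resp = es$resp,
       trace = trace)
}

# Split one cluster of the current model into two via random bipartitions,
# refit with EM, and return the best resulting (C+1)-subtype model state.
split_cluster <- function(Z, events, state, config, zsq) {
  es <- e_step(Z, events, state$sequences, state$f, config$sigma, zsq)
  hard <- max.col(es$resp, ties.method = "first")
  C <- length(state$sequences)
  best <- NULL
  for (c in seq_len(C)) {
    members <- which(hard == c)
    if (length(members) < config$min_cluster) next
    best_pair <- NULL
    for (b in seq_len(config$n_bipartitions)) {
      grp <- rep(1L, length(members))
      grp[sample.int(length(members), floor(length(members) / 2))] <- 2L
      s1 <- fit_sequence(Z[members[grp == 1L], , drop = FALSE], events,
                         sigma = config$sigma,
                         n_startpoints = config$split_startpoints)
      s2 <- fit_sequence(Z[members[grp == 2L], , drop = FALSE], events,
                         sigma = config$sigma,
                         n_startpoints = config$split_startpoints)
      pair_f <- c(mean(grp == 1L), mean(grp == 2L))
      pll <- mixture_loglik(Z[members, , drop = FALSE],
                            list(events = events, sigma = config$sigma),
                            sequences = list(s1$sequence, s2$sequence),
                            f = pair_f)
      if (is.null(best_pair) || pll > best_pair$ll) {
        best_pair <- list(s1 = s1$sequence, s2 = s2$sequence, ll = pll)
      }
    }
    if (is.null(best_pair)) next
    seqs <- state$sequences
    seqs <- append(seqs[-c], list(best_pair$s1, best_pair$s2))
    f <- c(state$f[-c], rep(state$f[c] / 2, 2))
    em <- em_fit(Z, events, seqs, f, config, zsq)
    if (is.null(best) || em$loglik > best$loglik) best <- em
  }
  if (is.null(best)) {
    stop("no cluster large enough to split (need >= ", config$min_cluster,
         " members)")
  }
  best
}

#' Fit the full subtype-and-stage model
#'
#' Jointly clusters subjects into `C` progression subtypes and fits each
#' subtype's event ordering. Fitting is hierarchical: the (C-1)-subtype
#' solution is extended by splitting the cluster whose split most improves
#' the likelihood (best of several random bipartitions), followed by
#' alternating soft assignment / sequence refit to convergence. Sequence
#' uncertainty is then estimated by Metropolis-Hastings MCMC with
#' single-event relocation proposals.
#'
#' @param Z z-score matrix (subjects x biomarkers) or a
#'   [zscore_matrix] object.
#' @param C number of subtypes (>= 1; must not exceed the subject count).
#' @param events a [zscore_events()] object.
#' @param config a [sustain_config()].
#' @return object of class `sustain_model`: `sequences` (per-subtype
#'   maximum-likelihood event orderings), `f` (subtype fractions), `sigma`,
#'   `loglik`, `ll_trace` (alternating-fit trace, nondecreasing), `mcmc`
#'   (thinned sequence samples per subtype) and the event set.
#' @export
fit_sustain <- function(Z, C, events, config = sustain_config()) {
  Z <- as_z_matrix(Z, events)
  if (C < 1L) stop("C must be >= 1")
  if (C > nrow(Z)) stop("C exceeds the number of subjects")
  with_seed(config$seed, {
    zsq <- rowSums(Z * Z)
    one <- fit_sequence(Z, events, sigma = config$sigma,
                        n_startpoints = config$n_startpoints)
    state <- list(sequences = list(one$sequence), f = 1, loglik = one$loglik,
                  trace = one$loglik)
    while (length(state$sequences) < C) {
      nxt <- split_cluster(Z, events, state, config, zsq)
      nxt$trace <- c(state$trace, nxt$trace)
      state <- nxt
    }
    model <- structure(list(
      events = events, C = C, sequences = state$sequences,
      f = if (C == 1L) 1 else state$f, sigma = config$sigma,
      loglik = state$loglik, ll_trace = state$trace,
      subtype_names = paste0("subtype", seq_len(C)),
      config = config, mcmc = NULL
    ), class = "sustain_model")
    if (config$mcmc_iter > 0) {
      model$mcmc <- run_mcmc(Z, model, iter = config$mcmc_iter,
                             burn = config$mcmc_burn,
                             thin = config$mcmc_thin, zsq = zsq)
    }
    model
  })
}

#' @export
print.sustain_model <- function(x, ...) {
  cat("Subtype progression model:", x$C, "subtype(s),",
      x$events$E, "events,", x$events$B, "biomarkers\n")
  cat("fractions:", paste(sprintf("%.3f", x$f), collapse = ", "), "\n")
  cat("log-likelihood:", format(x$loglik), "\n")
  if (!is.null(x$mcmc)) {
    cat("MCMC samples per subtype:", nrow(x$mcmc$samples[[1]]),
        sprintf("(acceptance %.2f)\n", x$mcmc$accept_rate))
  }
  invisible(x)
}

#' Attach interpretable subtype names to a fitted model
#'
#' @param model a `sustain_model`.
#' @param names character vector of length `model$C`.
#' @return the model with `subtype_names` replaced.
#' @export
name_subtypes <- function(model, names) {
  stopifnot(length(names) == model$C, !anyDuplicated(names))
  model$subtype_names <- names
  model
}

# Accept a zscore_matrix object or plain matrix; reorder columns to the
# event set's biomarkers and fail on missing ones.
as_z_matrix <- function(Z, events) {
  if (inherits(Z, "zscore_matrix")) Z <- Z$z
  Z <- as.matrix(Z)
  if (!is.null(colnames(Z))) {
    missing <- setdiff(events$biomarkers, colnames(Z))
    if (length(missing)) {
      stop("z-score matrix lacks modeled biomarkers: ",
           paste(missing, collapse = ", "))
    }
    Z <- Z[, events$biomarkers, drop = FALSE]
  } else if (ncol(Z) != events$B) {
    stop("unnamed z-score matrix with wrong number of columns")
  }
  if (anyNA(Z)) stop("NA z-scores are not allowed (no imputation)")
  storage.mode(Z) <- "double"
  Z
}
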