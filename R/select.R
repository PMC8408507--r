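#' Choose the number of subtypes by cross-validated information criterion
#'
#' For each candidate number of subtypes C, the model is fitted on k-1
#' training folds and the stage-marginalised mixture log-likelihood of the
#' held-out fold is accumulated. The criterion is
#' `CVIC(C) = -2 * (summed out-of-fold log-likelihood)`; the chosen C
#' minimises it, with a one-standard-error rule breaking near-ties toward
#' fewer subtypes (smallest C whose CVIC is within one SE of the minimum,
#' SE estimated from the spread of fold-level contributions).
#'
#' MCMC is skipped inside folds (only point fits are needed to score
#' held-out data), and the greedy restart budget is reduced relative to a
#' final fit; both are controlled by `config`.
#'
#' @param Z z-score matrix or [zscore_matrix] of the subjects to model.
#' @param events a [zscore_events()] object.
#' @param C_max largest number of subtypes considered (>= 1).
#' @param n_folds number of cross-validation folds (>= 2).
#' @param config a [sustain_config()]; its `seed` fixes fold assignment and
#'   all fits.
#' @return list with `chosen` (the selected C), `cvic` (per-C criterion),
#'   `se` (per-C standard error), and `fold_loglik` (n_folds x C_max matrix
#'   of out-of-fold log-likelihoods).
#' @export
select_n_subtypes <- function(Z, events, C_max, n_folds = 10,
                              config = sustain_config(
                                n_startpoints = 5, split_startpoints = 2,
                                n_bipartitions = 3, mcmc_iter = 0)) {
  Z <- as_z_matrix(Z, events)
  if (C_max < 1L) stop("C_max must be >= 1")
  if (C_max == 1L) {
    return(list(chosen = 1L, cvic = NA_real_, se = NA_real_,
                fold_loglik = NULL))
  }
  if (n_folds < 2L) stop("n_folds must be >= 2")
  N <- nrow(Z)
  if (n_folds > N) stop("more folds than subjects")
  with_seed(config$seed, {
    fold <- sample(rep_len(seq_len(n_folds), N))
    if (any(tabulate(fold, n_folds) == 0L)) stop("fold with zero subjects")
    fold_ll <- matrix(NA_real_, n_folds, C_max)
    fit_cfg <- config
    fit_cfg$seed <- NULL      # runs inside this function's seeded stream
    fit_cfg$mcmc_iter <- 0
    for (k in seq_len(n_folds)) {
      train <- Z[fold != k, , drop = FALSE]
      test <- Z[fold == k, , drop = FALSE]
      zsq_tr <- rowSums(train * train)
      one <- fit_sequence(train, events, sigma = fit_cfg$sigma,
                          n_startpoints = fit_cfg$n_startpoints)
      state <- list(sequences = list(one$sequence), f = 1,
                    loglik = one$loglik)
      score <- function(state) {
        mixture_loglik(test, list(events = events, sigma = fit_cfg$sigma),
                       sequences = state$sequences, f = state$f)
      }
      fold_ll[k, 1L] <- score(state)
      for (C in seq_len(C_max)[-1L]) {
        state <- split_cluster(train, events, state, fit_cfg, zsq_tr)
        fold_ll[k, C] <- score(state)
      }
    }
    cvic <- -2 * colSums(fold_ll)
    # SE of the summed criterion from fold-level spread
    se <- apply(-2 * fold_ll, 2L, stats::sd) * sqrt(n_folds)
    within <- which(cvic <= min(cvic) + se[which.min(cvic)])
    list(chosen = min(within), cvic = cvic, se = se, fold_loglik = fold_ll)
  })
}
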