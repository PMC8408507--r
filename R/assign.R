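#' Assign subject-visits to subtypes and stages
#'
#' Computes the posterior over (subtype, stage) for every row of a z-score
#' matrix under a fitted model, with a uniform prior over stages and —
#' by default — the fitted subtype fractions as the subtype prior. Because
#' all subtype trajectories coincide at stage 0, the stage-0 mass is pooled
#' across subtypes into a single "normal-appearing" probability; a row is
#' labeled normal-appearing when that probability exceeds every subtype's
#' stage >= 1 mass, and otherwise gets its most probable subtype. The
#' expected stage is the posterior-probability-weighted average stage.
#'
#' By default posteriors are averaged over the model's MCMC sequence
#' samples (capped at `max_samples` evenly spaced states), reflecting
#' ordering uncertainty; `use_mcmc = FALSE` uses the maximum-likelihood
#' sequences only.
#'
#' @param zmat a [zscore_matrix] (or plain matrix with biomarker columns).
#' @param model a fitted `sustain_model`.
#' @param subtype_prior `"fractions"` (fitted f_c) or `"flat"`.
#' @param use_mcmc average over MCMC sequence samples when available.
#' @param max_samples cap on the number of MCMC states used.
#' @return data.frame with one row per subject-visit: metadata columns (if
#'   available), `p_stage0`, one `p_<subtype>` column per subtype, `label`
#'   and `expected_stage`. `p_stage0 + sum(p_<subtype>) = 1` by
#'   construction.
#' @export
assign_cohort <- function(zmat, model, subtype_prior = c("fractions", "flat"),
                          use_mcmc = TRUE, max_samples = 200) {
  subtype_prior <- match.arg(subtype_prior)
  meta <- if (inherits(zmat, "zscore_matrix")) zmat$meta else NULL
  Z <- as_z_matrix(zmat, model$events)
  post <- posterior_mean(Z, model, subtype_prior, use_mcmc, max_samples)
  C <- model$C
  K <- model$events$E + 1L
  N <- nrow(Z)
  p_stage0 <- rowSums(post[, , 1L, drop = FALSE], dims = 1L)
  p_sub <- vapply(seq_len(C), function(c) {
    rowSums(post[, c, -1L, drop = FALSE])
  }, numeric(N))
  p_sub <- matrix(p_sub, nrow = N)
  stages <- array(rep(0:(K - 1L), each = N * C), dim = c(N, C, K))
  exp_stage <- rowSums(post * stages, dims = 1L)
  best <- max.col(p_sub, ties.method = "first")
  label <- ifelse(p_stage0 > p_sub[cbind(seq_len(N), best)],
                  "normal_appearing", model$subtype_names[best])
  if (C > 1L) {
    tied <- apply(p_sub, 1L, function(p) sum(p == max(p)) > 1L)
    n_ties <- sum(tied & label != "normal_appearing")
    if (n_ties > 0L) {
      warning(n_ties, " subtype tie(s) broken toward the lower subtype index")
    }
  }
  out <- data.frame(p_stage0 = p_stage0)
  for (c in seq_len(C)) out[[paste0("p_", model$subtype_names[c])]] <- p_sub[, c]
  out$label <- label
  out$expected_stage <- exp_stage
  if (!is.null(meta)) out <- cbind(meta, out)
  rownames(out) <- NULL
  out
}

# Mean posterior array (N x C x K) over the sequence states used.
posterior_mean <- function(Z, model, subtype_prior, use_mcmc, max_samples) {
  C <- model$C
  K <- model$events$E + 1L
  N <- nrow(Z)
  logf <- if (subtype_prior == "fractions") log(model$f) else rep(-log(C), C)
  states <- list(model$sequences)
  if (use_mcmc && !is.null(model$mcmc) &&
      nrow(model$mcmc$samples[[1]]) > 0L) {
    ns <- nrow(model$mcmc$samples[[1]])
    idx <- unique(round(seq(1L, ns, length.out = min(ns, max_samples))))
    states <- lapply(idx, function(i) {
      lapply(model$mcmc$samples, function(sm) sm[i, ])
    })
  }
  acc <- array(0, dim = c(N, C, K))
  for (st in states) {
    lp <- array(NA_real_, dim = c(N, C, K))
    for (c in seq_len(C)) {
      lp[, c, ] <- stage_logdens(Z, stage_means(model$events, st[[c]]),
                                 model$sigma) + logf[c] - log(K)
    }
    flat <- matrix(lp, nrow = N)
    norm <- row_logsumexp(flat)
    acc <- acc + array(exp(flat - norm), dim = c(N, C, K))
  }
  acc / length(states)
}

#' Assign a single subject's z-scores
#'
#' @param x named z-score vector (one value per modeled biomarker).
#' @param model fitted `sustain_model`.
#' @inheritParams assign_cohort
#' @return one-row data.frame as in [assign_cohort()].
#' @export
assign <- function(x, model, subtype_prior = c("fractions", "flat"),
                   use_mcmc = TRUE, max_samples = 200) {
  x <- as_z_row(x, model$events)
  assign_cohort(x, model, subtype_prior = match.arg(subtype_prior),
                use_mcmc = use_mcmc, max_samples = max_samples)
}

#' Probability-weighted expected stage of one subject
#'
#' `sum_{c,k} k P(c, k | x)`; lies in `[0, E]`.
#'
#' @inheritParams assign
#' @return nonnegative scalar.
#' @export
expected_stage <- function(x, model, subtype_prior = c("fractions", "flat"),
                           use_mcmc = TRUE, max_samples = 200) {
  assign(x, model, subtype_prior = match.arg(subtype_prior),
         use_mcmc = use_mcmc, max_samples = max_samples)$expected_stage
}
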