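# Stage-conditional Gaussian log-densities.
#
# Z: N x B matrix of sign-flipped z-scores; M: (E+1) x B matrix of expected
# values per stage (from stage_means). Returns N x (E+1) matrix with
# ll[i, k+1] = sum_b log Normal(Z[i,b]; M[k+1,b], sigma).
# zsq = rowSums(Z^2) may be passed to avoid recomputation in hot loops.
stage_logdens <- function(Z, M, sigma, zsq = NULL) {
  if (is.null(zsq)) zsq <- rowSums(Z * Z)
  K <- nrow(M)
  B <- ncol(Z)
  G <- tcrossprod(Z, M)                     # N x K
  m2 <- rowSums(M * M)
  sse <- (zsq - 2 * G) + matrix(m2, nrow(Z), K, byrow = TRUE)
  (-0.5 / sigma^2) * sse - B * log(sigma) - 0.5 * B * log(2 * pi)
}

# Per-subject stage-marginalised log-likelihood under one sequence:
# log (1/(E+1)) sum_k prod_b Normal(x_b; g_b(k), sigma).
marginal_loglik <- function(Z, M, sigma, zsq = NULL) {
  ll <- stage_logdens(Z, M, sigma, zsq)
  mx <- ll[cbind(seq_len(nrow(ll)), max.col(ll, ties.method = "first"))]
  mx + log(rowSums(exp(ll - mx))) - log(ncol(ll))
}

# Per-subject stage-marginalised log-likelihood of one sequence, through the
# compiled kernel.
seq_margll <- function(events, sequence, Z, sigma) {
  cpp_marg_loglik(as.integer(sequence), Z, sigma, events$bio_start,
                  events$threshold, events$z_max)
}

# Weighted total marginal log-likelihood of a sequence (EM M-step objective;
# weights = NULL gives the plain data log-likelihood of a one-subtype model).
sequence_loglik <- function(events, sequence, Z, sigma, weights = NULL,
                            zsq = NULL) {
  cpp_seq_loglik(as.integer(sequence), Z, sigma, events$bio_start,
                 events$threshold, events$z_max, weights)
}

# N x C matrix of per-subtype stage-marginalised log-likelihoods.
subtype_margloglik <- function(Z, model, sequences = NULL, zsq = NULL) {
  sequences <- sequences %||% model$sequences
  vapply(sequences, function(s) {
    seq_margll(model$events, s, Z, model$sigma)
  }, numeric(nrow(Z)))
}

# Total mixture log-likelihood sum_i log sum_c f_c P(x_i | c).
mixture_loglik <- function(Z, model, sequences = NULL, f = NULL, zsq = NULL) {
  f <- f %||% model$f
  ml <- subtype_margloglik(Z, model, sequences, zsq)
  lw <- sweep(ml, 2L, log(f), "+")
  sum(row_logsumexp(lw))
}

#' Per-(subtype, stage) likelihood of one subject's z-scores
#'
#' Evaluates `L(x | c, k) = prod_b Normal(x_b; g_b^c(k), sigma)` for every
#' subtype c and stage k of a fitted model, the quantity from which subtype
#' memberships (marginalised over stage with a uniform 1/(E+1) prior) and
#' stage posteriors are built.
#'
#' @param x named numeric vector (or single-row matrix) of sign-flipped
#'   z-scores, one value per modeled biomarker. Missing biomarkers are an
#'   error; no imputation is performed.
#' @param model a fitted [sustain_model] (see [fit_sustain()]).
#' @param log return log-likelihoods?
#' @return C x (E+1) matrix; rows are subtypes, columns stages 0..E.
#' @export
subject_likelihood <- function(x, model, log = FALSE) {
  x <- as_z_row(x, model$events)
  ll <- t(vapply(model$sequences, function(s) {
    drop(stage_logdens(x, stage_means(model$events, s), model$sigma))
  }, numeric(model$events$E + 1L)))
  dimnames(ll) <- list(model$subtype_names, paste0("stage", 0:model$events$E))
  if (log) ll else exp(ll)
}

# Coerce a named vector / 1-row data.frame to a 1 x B matrix in the event
# set's biomarker order; hard error on missing or NA biomarkers.
as_z_row <- function(x, events) {
  if (is.data.frame(x)) x <- unlist(x)
  if (is.matrix(x)) x <- drop(x)
  if (is.null(names(x))) {
    if (length(x) != events$B) stop("unnamed z-score vector of wrong length")
    names(x) <- events$biomarkers
  }
  missing <- setdiff(events$biomarkers, names(x))
  if (length(missing)) {
    stop("missing biomarker values: ", paste(missing, collapse = ", "))
  }
  x <- x[events$biomarkers]
  if (anyNA(x)) stop("NA z-scores are not allowed (no imputation)")
  matrix(x, nrow = 1L, dimnames = list(NULL, events$biomarkers))
}
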