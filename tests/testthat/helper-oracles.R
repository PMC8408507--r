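# Independent oracles used across the suite. These deliberately avoid the
# package's computational path: trajectories via stats::approx, likelihoods
# by direct enumeration with dnorm, OLS by the normal equations.

tau_seq <- function(a, b) {
  stats::cor(order(a), order(b), method = "kendall")
}

# Piecewise-linear expected z-score of one biomarker, via stats::approx.
oracle_stage_matrix <- function(events, sequence) {
  E <- events$E
  sapply(seq_len(events$B), function(i) {
    ids <- events$events_by_bio[[i]]
    pos <- match(ids, sequence)
    keep <- pos < E
    stats::approx(c(0, pos[keep], E),
                  c(0, events$threshold[ids][keep], events$z_max[i]),
                  xout = 0:E)$y
  })
}

# Likelihood table by direct enumeration: L(x | c, k) = prod_b dnorm.
oracle_likelihood_table <- function(model, x) {
  ev <- model$events
  t(sapply(model$sequences, function(s) {
    M <- oracle_stage_matrix(ev, s)
    sapply(0:ev$E, function(k) prod(stats::dnorm(x, M[k + 1L, ], model$sigma)))
  }))
}

# Stage-marginalised log-likelihood of one sequence for a data matrix.
oracle_marginal_loglik <- function(events, sequence, Z, sigma) {
  M <- oracle_stage_matrix(events, sequence)
  apply(Z, 1L, function(x) {
    log(mean(sapply(0:events$E, function(k) {
      prod(stats::dnorm(x, M[k + 1L, ], sigma))
    })))
  })
}

# Posterior over (subtype, stage) by enumeration with uniform stage prior.
oracle_posterior <- function(model, x, use_fractions = TRUE) {
  L <- oracle_likelihood_table(model, x)
  f <- if (use_fractions) model$f else rep(1 / model$C, model$C)
  P <- L * f
  P / sum(P)
}

# All permutations of 1..n (n small), as a list.
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (i in 0:(n - 1L)) out[[length(out) + 1L]] <- append(p, n, after = i)
  }
  out
}

# All valid event orderings of a small event set.
all_valid_sequences <- function(events) {
  Filter(function(s) is_valid_sequence(events, s),
         all_permutations(events$E))
}

# Closed-form OLS via the normal equations (independent of lm).
oracle_ols <- function(X, y) {
  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(solve(xtx)) * s2))
}

# Hand-built model object for toy tests.
toy_model <- function(events, sequences, f = NULL, sigma = 1) {
  C <- length(sequences)
  structure(list(events = events, C = C, sequences = sequences,
                 f = f %||% rep(1 / C, C), sigma = sigma,
                 loglik = NA_real_, ll_trace = NULL,
                 subtype_names = paste0("subtype", seq_len(C)),
                 config = NULL, mcmc = NULL),
            class = "sustain_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
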