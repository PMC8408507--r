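# Metropolis-Hastings over event orderings. At each iteration one subtype's
# sequence receives a single-event relocation proposal (uniform event,
# uniform valid slot); subtype fractions stay at their maximum-likelihood
# values. The proposal is symmetric: removing an event and reinserting it
# does not change the slot count between its threshold siblings.
run_mcmc <- function(Z, model, iter, burn, thin, zsq = NULL) {
  events <- model$events
  zsq <- zsq %||% rowSums(Z * Z)
  C <- model$C
  seqs <- model$sequences
  ml <- vapply(seqs, function(s) {
    seq_margll(events, s, Z, model$sigma)
  }, numeric(nrow(Z)))
  logf <- log(model$f)
  total_ll <- function(ml) sum(row_logsumexp(sweep(ml, 2L, logf, "+")))
  cur_ll <- total_ll(ml)
  keep <- seq.int(burn + thin, iter, by = thin)
  samples <- lapply(seq_len(C), function(c) {
    matrix(NA_integer_, nrow = length(keep), ncol = events$E)
  })
  ll_kept <- numeric(length(keep))
  n_acc <- 0L
  j <- 0L
  for (it in seq_len(iter)) {
    c <- if (C == 1L) 1L else sample.int(C, 1L)
    s <- seqs[[c]]
    e <- sample.int(events$E, 1L)
    others <- s[s != e]
    slots <- insertion_slots(events, others, e)
    cand <- append(others, e, after = slots[sample.int(length(slots), 1L)] - 1L)
    ml_c <- seq_margll(events, cand, Z, model$sigma)
    ml_new <- ml
    ml_new[, c] <- ml_c
    new_ll <- total_ll(ml_new)
    if (log(stats::runif(1L)) < new_ll - cur_ll) {
      seqs[[c]] <- cand
      ml <- ml_new
      cur_ll <- new_ll
      n_acc <- n_acc + 1L
    }
    if (j < length(keep) && it == keep[j + 1L]) {
      j <- j + 1L
      for (cc in seq_len(C)) samples[[cc]][j, ] <- seqs[[cc]]
      ll_kept[j] <- cur_ll
    }
  }
  list(samples = samples, loglik = ll_kept, accept_rate = n_acc / iter)
}

#' Positional variance of a fitted model
#'
#' For each subtype, the posterior probability that each event occupies
#' each stage, estimated as the fraction of MCMC sequence samples placing
#' the event there. This is the matrix behind the classic positional
#' variance diagram: a sharply fitted ordering concentrates each row on one
#' stage; uncertainty spreads it out.
#'
#' @param model a fitted `sustain_model` with a nonempty MCMC sample.
#' @return object of class `positional_variance`: a list with one
#'   E x E matrix per subtype (rows = events in model-table order, columns =
#'   stages 1..E; each row sums to 1).
#' @export
positional_variance <- function(model) {
  if (is.null(model$mcmc) || nrow(model$mcmc$samples[[1]]) == 0L) {
    stop("model has no MCMC sample; refit with mcmc_iter > 0")
  }
  events <- model$events
  out <- lapply(seq_len(model$C), function(c) {
    sm <- model$mcmc$samples[[c]]
    P <- matrix(0, nrow = events$E, ncol = events$E,
                dimnames = list(
                  paste0(events$table$biomarker, "_z", events$table$threshold),
                  paste0("stage", seq_len(events$E))))
    for (i in seq_len(nrow(sm))) {
      pos <- order(sm[i, ])  # pos[e] = stage of event e
      P[cbind(seq_len(events$E), pos)] <- P[cbind(seq_len(events$E), pos)] + 1
    }
    P / nrow(sm)
  })
  names(out) <- model$subtype_names
  structure(out, class = "positional_variance")
}
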