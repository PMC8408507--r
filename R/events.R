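#' Define the z-score event set of a progression model
#'
#' A z-score event is a biomarker (regional volume) reaching one of its
#' z-score thresholds. The progression model is an ordering of all events:
#' stage k means the first k events have occurred. Thresholds default to
#' 1, 2 and 3 with a maximum (end-of-progression) z-score of 5.
#'
#' @param biomarkers character vector of biomarker (region) names.
#' @param z_thresholds numeric vector of strictly increasing positive
#'   thresholds shared by all biomarkers, or a named list with one such
#'   vector per biomarker.
#' @param z_max positive scalar (or vector per biomarker) giving the
#'   asymptotic z-score reached at the final stage; must exceed every
#'   threshold.
#' @return An object of class `zscore_events`: the event table plus index
#'   vectors used by the model internals. `E` is the total number of events
#'   (= number of stages beyond stage 0).
#' @export
#' @examples
#' ev <- zscore_events(c("hippocampus", "amygdala"))
#' ev$E  # 6 events: 2 biomarkers x 3 thresholds
zscore_events <- function(biomarkers, z_thresholds = c(1, 2, 3), z_max = 5) {
  stopifnot(is.character(biomarkers), length(biomarkers) >= 1,
            !anyDuplicated(biomarkers))
  B <- length(biomarkers)
  if (!is.list(z_thresholds)) {
    z_thresholds <- stats::setNames(rep(list(z_thresholds), B), biomarkers)
  }
  if (length(z_max) == 1L) z_max <- stats::setNames(rep(z_max, B), biomarkers)
  z_thresholds <- z_thresholds[biomarkers]
  z_max <- z_max[biomarkers]
  for (b in biomarkers) {
    thr <- z_thresholds[[b]]
    if (any(diff(thr) <= 0) || any(thr <= 0)) {
      stop("z_thresholds must be strictly increasing and positive (", b, ")")
    }
    if (any(thr >= z_max[[b]])) {
      stop("all z_thresholds must be below z_max (", b, ")")
    }
  }
  tab <- do.call(rbind, lapply(seq_len(B), function(i) {
    data.frame(biomarker = biomarkers[i],
               bio_idx = i,
               threshold = z_thresholds[[biomarkers[i]]])
  }))
  tab$event <- seq_len(nrow(tab))
  structure(list(
    table = tab[, c("event", "biomarker", "bio_idx", "threshold")],
    biomarkers = biomarkers,
    B = B,
    E = nrow(tab),
    bio_idx = tab$bio_idx,
    threshold = tab$threshold,
    z_max = as.numeric(z_max),
    events_by_bio = split(tab$event, tab$bio_idx),
    # 0-based offsets of each biomarker's contiguous event-id block,
    # consumed by the compiled likelihood kernel
    bio_start = c(0L, cumsum(lengths(split(tab$event, tab$bio_idx))))
  ), class = "zscore_events")
}

#' @export
print.zscore_events <- function(x, ...) {
  cat("z-score event set:", x$B, "biomarkers,", x$E, "events\n")
  invisible(x)
}

#' Check that a sequence is a valid event ordering
#'
#' Valid means: a permutation of all events in which each biomarker's
#' thresholds appear in increasing order (a volume cannot reach z = 2
#' before z = 1).
#'
#' @param events a [zscore_events()] object.
#' @param sequence integer vector of event ids.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_sequence <- function(events, sequence) {
  if (length(sequence) != events$E) return(FALSE)
  if (!setequal(sequence, seq_len(events$E))) return(FALSE)
  pos <- order(sequence)  # pos[e] = position of event e
  for (ids in events$events_by_bio) {
    if (is.unsorted(pos[ids], strictly = TRUE)) return(FALSE)
  }
  TRUE
}

# Random valid event ordering: shuffle all events, then rearrange each
# biomarker's events so thresholds ascend along the sequence.
random_sequence <- function(events) {
  s <- sample.int(events$E)
  for (ids in events$events_by_bio) {
    s[sort(match(ids, s))] <- ids
  }
  s
}

#' Expected z-score trajectories implied by an event ordering
#'
#' For each biomarker the expected z-score is piecewise linear in stage,
#' anchored at (0, 0), at (position of each threshold event, threshold) and
#' at (E, z_max). Returns the full (E+1) x B matrix of expected values; the
#' single-biomarker convenience accessor is [trajectory()].
#'
#' @param events a [zscore_events()] object.
#' @param sequence valid event ordering.
#' @return numeric matrix with E+1 rows (stages 0..E) and one column per
#'   biomarker.
#' @export
stage_means <- function(events, sequence) {
  E <- events$E
  pos <- order(sequence)
  out <- matrix(0, nrow = E + 1L, ncol = events$B,
                dimnames = list(NULL, events$biomarkers))
  xout <- 0:E
  for (i in seq_len(events$B)) {
    ids <- events$events_by_bio[[i]]
    px <- pos[ids]
    py <- events$threshold[ids]
    # the end anchor (E, z_max) wins if the top threshold event sits at E
    keep <- px < E
    x <- c(0, px[keep], E)
    y <- c(0, py[keep], events$z_max[i])
    # inline linear interpolation on the integer stage grid (hot path)
    j <- findInterval(xout, x, rightmost.closed = TRUE)
    out[, i] <- y[j] + (y[j + 1L] - y[j]) * (xout - x[j]) / (x[j + 1L] - x[j])
  }
  out[E + 1L, ] <- events$z_max
  out
}

#' Expected z-score of one biomarker at a given stage
#'
#' @param events a [zscore_events()] object.
#' @param sequence valid event ordering.
#' @param biomarker biomarker name.
#' @param k integer stage(s) in 0..E.
#' @return expected z-score(s) g_b(k); monotone nondecreasing in k.
#' @export
#' @examples
#' ev <- zscore_events("a", z_thresholds = 1, z_max = 5)
#' # toy: more biomarkers needed for E = 4; see stage_means() for the matrix
trajectory <- function(events, sequence, biomarker, k) {
  if (!biomarker %in% events$biomarkers) {
    stop("unknown biomarker: ", biomarker)
  }
  stopifnot(all(k == floor(k)), all(k >= 0), all(k <= events$E))
  M <- stage_means(events, sequence)
  M[k + 1L, biomarker]
}
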