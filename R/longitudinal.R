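#' Longitudinal consistency of subtype and stage assignments
#'
#' Compares every follow-up visit's assignment with the same subject's
#' baseline (earliest) visit under a model fitted at baseline: tabulates
#' label transitions (same label, normal-appearing to subtype, subtype to
#' normal-appearing, subtype to a different subtype) and collects
#' baseline/follow-up stage pairs with the inter-visit interval.
#'
#' @param assignments assignment table ([assign_cohort()]) covering
#'   baseline and follow-up visits, with `subject_id`, `visit` (ordered in
#'   time within subject; assumed annual), `label` and `expected_stage`.
#' @return object of class `consistency_report`: `transitions` (named
#'   counts summing to the number of follow-up visits), `n_followups`,
#'   `frac_same_label`, `frac_stage_nondecreasing`, and `stage_pairs`
#'   (per follow-up visit: baseline and follow-up stage, labels, interval
#'   in years).
#' @export
consistency <- function(assignments) {
  key <- paste(assignments$subject_id, assignments$visit)
  if (anyDuplicated(key)) stop("duplicate (subject, visit) keys")
  ord <- order(assignments$subject_id, assignments$visit)
  a <- assignments[ord, , drop = FALSE]
  base_idx <- !duplicated(a$subject_id)
  base <- a[base_idx, , drop = FALSE]
  fu <- a[!base_idx, , drop = FALSE]
  if (nrow(fu) > 0L && !all(fu$subject_id %in% base$subject_id)) {
    stop("follow-up visit without a baseline visit")
  }
  m <- match(fu$subject_id, base$subject_id)
  b_lab <- base$label[m]
  f_lab <- fu$label
  na <- "normal_appearing"
  type <- ifelse(b_lab == f_lab, "same",
          ifelse(b_lab == na, "normal_to_subtype",
          ifelse(f_lab == na, "subtype_to_normal", "subtype_to_subtype")))
  transitions <- c(same = sum(type == "same"),
                   normal_to_subtype = sum(type == "normal_to_subtype"),
                   subtype_to_normal = sum(type == "subtype_to_normal"),
                   subtype_to_subtype = sum(type == "subtype_to_subtype"))
  stage_pairs <- data.frame(
    subject_id = fu$subject_id, visit = fu$visit,
    baseline_label = b_lab, followup_label = f_lab, transition = type,
    baseline_stage = base$expected_stage[m],
    followup_stage = fu$expected_stage,
    interval_years = fu$visit - base$visit[m],
    stringsAsFactors = FALSE, row.names = NULL)
  n_fu <- nrow(fu)
  structure(list(
    transitions = transitions,
    n_followups = n_fu,
    frac_same_label = if (n_fu) unname(transitions["same"]) / n_fu else NA_real_,
    # stages are integers in the model; expected stages are compared on the
    # integer grid so sub-stage jitter does not count as regression
    frac_stage_nondecreasing = if (n_fu) {
      mean(round(stage_pairs$followup_stage) >=
             round(stage_pairs$baseline_stage))
    } else NA_real_,
    stage_pairs = stage_pairs
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("longitudinal consistency over", x$n_followups, "follow-up visits\n")
  print(x$transitions)
  cat(sprintf("same label: %.1f%%; stage nondecreasing: %.1f%%\n",
              100 * x$frac_same_label, 100 * x$frac_stage_nondecreasing))
  invisible(x)
}
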