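#' Bonferroni-corrected significance threshold
#'
#' `0.05 / m`, reported raw and rounded to one significant figure (the
#' convention used when quoting family-wise thresholds such as 0.001 for a
#' 43-item clinical family and 0.005 for an 11-item neuropsychology
#' battery).
#'
#' @param m number of tests in the family.
#' @param alpha family-wise level.
#' @return list with `raw` and `rounded`.
#' @export
#' @examples
#' bonferroni_threshold(43)$rounded  # 0.001
#' bonferroni_threshold(11)$rounded  # 0.005
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(m >= 1)
  raw <- alpha / m
  list(raw = raw, rounded = signif(raw, 1))
}

stat_row <- function(test, variable, group1, group2, statistic, p, n1, n2,
                     bonferroni_m = 1, note = "") {
  thr <- bonferroni_threshold(bonferroni_m)
  data.frame(test = test, variable = variable, group1 = group1,
             group2 = group2, statistic = statistic, p = p,
             n1 = n1, n2 = n2,
             sig_nominal = !is.na(p) & p < 0.05,
             sig_bonferroni = !is.na(p) & p < thr$raw,
             note = note, stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise group comparisons of a single variable
#'
#' Welch two-sample t-tests for continuous variables and chi-square tests
#' (without Yates continuity correction by default) for categorical ones,
#' over all pairs of groups — the demographic comparison layer across the
#' normal-appearing group and each subtype.
#'
#' @param df data.frame containing `variable` and `grouping` columns.
#' @param variable column to compare.
#' @param grouping column defining the groups.
#' @param type `"auto"` (numeric = continuous), `"continuous"` or
#'   `"categorical"`.
#' @param var_equal assume equal variances in the t-test (default Welch).
#' @param correct apply Yates continuity correction in 2x2 chi-square.
#' @param bonferroni_m family size for the Bonferroni flag.
#' @return data.frame of `StatResult` rows, one per group pair.
#' @export
compare_groups <- function(df, variable, grouping,
                           type = c("auto", "continuous", "categorical"),
                           var_equal = FALSE, correct = FALSE,
                           bonferroni_m = 1) {
  type <- match.arg(type)
  g <- as.character(df[[grouping]])
  v <- df[[variable]]
  ok <- !is.na(g) & !is.na(v)
  g <- g[ok]; v <- v[ok]
  groups <- sort(unique(g))
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (type == "auto") {
    type <- if (is.numeric(v)) "continuous" else "categorical"
  }
  out <- list()
  for (i in seq_along(groups)[-length(groups)]) {
    for (j in seq.int(i + 1L, length(groups))) {
      vi <- v[g == groups[i]]
      vj <- v[g == groups[j]]
      if (length(vi) == 0L || length(vj) == 0L) stop("empty group")
      if (type == "continuous") {
        if (length(vi) < 2L || length(vj) < 2L) stop("need >= 2 obs per group")
        if (stats::sd(vi) == 0 && stats::sd(vj) == 0) {
          out[[length(out) + 1L]] <- stat_row(
            "t", variable, groups[i], groups[j], NA_real_, NA_real_,
            length(vi), length(vj), bonferroni_m,
            note = "zero variance; p undefined")
          next
        }
        tt <- stats::t.test(vi, vj, var.equal = var_equal)
        out[[length(out) + 1L]] <- stat_row(
          "t", variable, groups[i], groups[j],
          unname(tt$statistic), tt$p.value, length(vi), length(vj),
          bonferroni_m)
      } else {
        tab <- table(factor(c(rep(groups[i], length(vi)),
                              rep(groups[j], length(vj)))),
                     c(vi, vj))
        ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
        out[[length(out) + 1L]] <- stat_row(
          "chisq", variable, groups[i], groups[j],
          unname(ct$statistic), ct$p.value, length(vi), length(vj),
          bonferroni_m,
          note = if (any(ct$expected < 5)) "low expected counts" else "")
      }
    }
  }
  do.call(rbind, out)
}

#' Mutation vs subtype association tests
#'
#' For each mutation label among subtypable carriers, a chi-square test of
#' the 2 x C table counting carriers with that mutation vs all other
#' mutations against assigned subtype. Mutations carried by a single
#' subtypable individual are flagged low-n rather than dropped.
#'
#' @param assignments assignment table ([assign_cohort()]) including a
#'   `mutation` column; normal-appearing rows are excluded here.
#' @param correct Yates continuity correction (default off).
#' @return data.frame of `StatResult` rows, one per mutation, plus the
#'   underlying counts as a `counts` attribute.
#' @export
mutation_subtype_association <- function(assignments, correct = FALSE) {
  sub <- assignments[assignments$label != "normal_appearing", , drop = FALSE]
  if (nrow(sub) == 0L) stop("no subtypable individuals")
  muts <- sort(unique(sub$mutation))
  counts <- table(sub$mutation, sub$label)
  out <- lapply(muts, function(m) {
    is_m <- factor(ifelse(sub$mutation == m, m, "all_others"),
                   levels = c(m, "all_others"))
    tab <- table(is_m, sub$label)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    stat_row("chisq", "subtype_assignment", m, "all_others",
             unname(ct$statistic), ct$p.value,
             sum(sub$mutation == m), sum(sub$mutation != m),
             note = if (sum(sub$mutation == m) < 2L) "low-n" else "")
  })
  out <- do.call(rbind, out)
  attr(out, "counts") <- counts
  out
}

#' Stage-adjusted linear models of clinical scores
#'
#' Fits `score ~ subtype + stage + age + sex` by ordinary least squares for
#' each score, over subtypable individuals only, with two-sided Wald p
#' values and a Bonferroni threshold derived from the number of scores
#' tested. Rows with missing values are dropped listwise with a logged
#' count.
#'
#' @param scores data.frame with `subject_id`, `visit` and one column per
#'   score.
#' @param assignments assignment table with `label` and `expected_stage`
#'   (plus `age`, `sex` unless given separately in `covariates`).
#' @param covariates optional data.frame with `subject_id`, `visit`,
#'   `age`, `sex` overriding the assignment table's columns.
#' @param score_cols score columns to model (default: all non-key columns).
#' @return data.frame: one row per (score, term) with estimate, SE, t,
#'   p and significance flags; Bonferroni family size = number of scores.
#'   Unidentifiable (aliased) coefficients are flagged.
#' @export
score_model <- function(scores, assignments, covariates = NULL,
                        score_cols = NULL) {
  score_cols <- score_cols %||% setdiff(names(scores),
                                        c("subject_id", "visit"))
  sub <- assignments[assignments$label != "normal_appearing", , drop = FALSE]
  if (!is.null(covariates)) {
    sub <- merge(sub[, setdiff(names(sub), c("age", "sex"))], covariates,
                 by = c("subject_id", "visit"))
  }
  df <- merge(sub, scores, by = c("subject_id", "visit"))
  if (nrow(df) == 0L) stop("no subtypable rows with scores")
  m <- length(score_cols)
  thr <- bonferroni_threshold(m)
  out <- list()
  for (sc in score_cols) {
    d <- data.frame(score = df[[sc]],
                    subtype = factor(df$label),
                    stage = df$expected_stage,
                    age = df$age,
                    sex = as.numeric(df$sex == "male"))
    n0 <- nrow(d)
    d <- stats::na.omit(d)
    if (n0 - nrow(d) > 0L) {
      msg("score %s: dropped %d row(s) with missing values (listwise)",
          sc, n0 - nrow(d))
    }
    fit <- stats::lm(score ~ subtype + stage + age + sex, data = d)
    cf <- summary(fit)$coefficients
    aliased <- names(which(is.na(stats::coef(fit))))
    rows <- data.frame(score = sc, term = rownames(cf),
                       estimate = cf[, 1L], se = cf[, 2L],
                       t = cf[, 3L], p = cf[, 4L],
                       n = nrow(d),
                       sig_nominal = cf[, 4L] < 0.05,
                       sig_bonferroni = cf[, 4L] < thr$raw,
                       unidentifiable = FALSE,
                       stringsAsFactors = FALSE, row.names = NULL)
    if (length(aliased)) {
      rows <- rbind(rows, data.frame(
        score = sc, term = aliased, estimate = NA_real_, se = NA_real_,
        t = NA_real_, p = NA_real_, n = nrow(d), sig_nominal = FALSE,
        sig_bonferroni = FALSE, unidentifiable = TRUE,
        stringsAsFactors = FALSE))
    }
    out[[sc]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "bonferroni") <- c(m = m, raw = thr$raw, rounded = thr$rounded)
  res
}

#' Correlation between expected stage and estimated years from onset
#'
#' Pearson correlation of model stage with EYO across subtypable
#' individuals, overall and within each subtype.
#'
#' @param assignments assignment table with `expected_stage`, `eyo`,
#'   `label`.
#' @return data.frame with rows `overall` and one per subtype: `r`, `p`,
#'   `n`.
#' @export
stage_eyo_correlation <- function(assignments) {
  sub <- assignments[assignments$label != "normal_appearing" &
                       !is.na(assignments$eyo), , drop = FALSE]
  one <- function(d, name) {
    if (nrow(d) < 3L) {
      return(data.frame(group = name, r = NA_real_, p = NA_real_,
                        n = nrow(d), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(d$expected_stage, d$eyo)
    data.frame(group = name, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(d), stringsAsFactors = FALSE)
  }
  if (nrow(sub) < 3L) stop("need at least 3 subtypable rows with EYO")
  res <- rbind(one(sub, "overall"),
               do.call(rbind, lapply(sort(unique(sub$label)), function(l) {
                 one(sub[sub$label == l, , drop = FALSE], l)
               })))
  rownames(res) <- NULL
  res
}

#' Rank-based two-group comparison (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test using the normal approximation with tie
#' correction — the comparison used between symptomatic carriers of each
#' subtype and noncarrier relatives, where scores are ordinal or skewed.
#'
#' @param x,y numeric samples for the two groups.
#' @param group1,group2 labels for reporting.
#' @param variable variable name for reporting.
#' @param bonferroni_m family size for the Bonferroni flag.
#' @return one `StatResult` row; the statistic is U for the first group.
#'   All-tied data yield p = 1 with a note.
#' @export
rank_compare <- function(x, y, group1 = "group1", group2 = "group2",
                         variable = "score", bonferroni_m = 1) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  if (length(unique(c(x, y))) == 1L) {
    return(stat_row("mann_whitney_u", variable, group1, group2,
                    length(x) * length(y) / 2, 1,
                    length(x), length(y), bonferroni_m,
                    note = "all observations tied; p = 1"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  stat_row("mann_whitney_u", variable, group1, group2,
           unname(wt$statistic), wt$p.value, length(x), length(y),
           bonferroni_m)
}
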