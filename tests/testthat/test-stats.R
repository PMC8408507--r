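test_that("Bonferroni thresholds reproduce the printed family levels", {
  expect_equal(bonferroni_threshold(43)$rounded, 0.001)
  expect_equal(bonferroni_threshold(11)$rounded, 0.005)
  expect_equal(bonferroni_threshold(43)$raw, 0.05 / 43)
  expect_error(bonferroni_threshold(0))
})

test_that("group comparisons use Welch t and chi-square as appropriate", {
  # equal categorical distributions: chi-square statistic 0, p = 1
  df <- data.frame(g = rep(c("x", "y"), each = 20),
                   v = rep(c("m", "f"), 20))
  r <- compare_groups(df, "v", "g", type = "categorical")
  expect_equal(r$p, 1)
  expect_equal(r$statistic, 0)

  # a 2-SD mean shift at n = 50 per group is essentially always detected
  set.seed(90)
  df2 <- data.frame(g = rep(c("x", "y"), each = 50),
                    v = c(rnorm(50, 0), rnorm(50, 2)))
  r2 <- compare_groups(df2, "v", "g")
  expect_lt(r2$p, 0.001)
  expect_equal(r2$test, "t")

  # zero-variance groups are flagged, not tested
  df3 <- data.frame(g = rep(c("x", "y"), each = 5), v = rep(1, 10))
  r3 <- compare_groups(df3, "v", "g")
  expect_true(is.na(r3$p))
  expect_match(r3$note, "zero variance")

  expect_error(compare_groups(df[df$g == "x", ], "v", "g"), "2 groups")
})

test_that("the 2x2 association example matches the closed-form chi-square", {
  # counts [[9,1],[1,13]]: mutation vs subtype
  df <- data.frame(
    mutation = c(rep("P301L", 10), rep("other", 14)),
    label = c(rep("frontotemporal", 9), "temporal",
              "frontotemporal", rep("temporal", 13)))
  r <- compare_groups(df, "label", "mutation", type = "categorical")
  a <- 9; b <- 1; c <- 1; d <- 13; n <- a + b + c + d
  chi2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(r$statistic, chi2, tolerance = 1e-12)
  expect_equal(r$p, pchisq(chi2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(r$p, 0.05)
})

test_that("mutation-subtype association finds one-to-one mappings", {
  asg <- data.frame(
    subject_id = sprintf("s%02d", 1:24), visit = 1,
    mutation = c(rep("R406W", 7), rep("P301L", 10), rep("IVS10+16", 7)),
    label = c(rep("temporal", 7), rep("frontotemporal", 9), "temporal",
              rep("temporal", 7)))
  r <- mutation_subtype_association(asg)
  expect_lt(r$p[r$group1 == "R406W"], 0.05)
  expect_lt(r$p[r$group1 == "P301L"], 0.001)
  counts <- attr(r, "counts")
  expect_equal(unname(counts["R406W", "temporal"]), 7)

  # a 50/50 split carries no association
  asg2 <- data.frame(subject_id = sprintf("s%02d", 1:20), visit = 1,
                     mutation = rep(c("A", "B"), each = 10),
                     label = rep(c("temporal", "frontotemporal"), 10))
  r2 <- mutation_subtype_association(asg2)
  expect_equal(r2$p, c(1, 1), tolerance = 1e-12)

  # normal-appearing rows are excluded
  asg3 <- rbind(asg, data.frame(subject_id = "s99", visit = 1,
                                mutation = "R406W",
                                label = "normal_appearing"))
  r3 <- mutation_subtype_association(asg3)
  expect_equal(r3$n1[r3$group1 == "R406W"], 7)
})

test_that("permuted mutation labels give uniform association p values", {
  set.seed(91)
  base_mut <- c(rep("A", 12), rep("B", 12))
  ps <- replicate(200, {
    lab <- sample(rep(c("temporal", "frontotemporal"), each = 12))
    asg <- data.frame(subject_id = sprintf("s%02d", 1:24), visit = 1,
                      mutation = base_mut, label = lab)
    mutation_subtype_association(asg)$p[1]
  })
  # discrete test: compare against its own permutation null rather than
  # exact uniformity
  expect_gt(mean(ps > 0.05), 0.85)
  expect_gt(min(ps), 0)
})

test_that("the stage-adjusted score model matches the OLS oracle", {
  set.seed(92)
  n <- 200
  asg <- data.frame(
    subject_id = sprintf("s%03d", 1:n), visit = 1,
    label = sample(c("temporal", "frontotemporal"), n, TRUE),
    expected_stage = runif(n, 0, 18),
    age = runif(n, 30, 70),
    sex = sample(c("female", "male"), n, TRUE))
  male <- as.numeric(asg$sex == "male")
  ft <- as.numeric(asg$label == "temporal")  # factor level order: f < t
  y <- 5 - 1 * asg$expected_stage + 0.1 * asg$age + 2 * ft +
    rnorm(n, 0, 1)
  scores <- data.frame(subject_id = asg$subject_id, visit = 1, sc = y)
  r <- score_model(scores, asg)
  est_stage <- r$estimate[r$term == "stage"]
  expect_lt(abs(est_stage - (-1)), 0.1)
  X <- cbind(1, ft, asg$expected_stage, asg$age, male)
  fit <- oracle_ols(X, y)
  expect_equal(est_stage, unname(fit$beta[3]), tolerance = 1e-8)
  expect_equal(r$estimate[grepl("subtype", r$term)], unname(fit$beta[2]),
               tolerance = 1e-8)

  # null subtype effect stays within 2 SE
  y0 <- 5 - 1 * asg$expected_stage + rnorm(n)
  r0 <- score_model(data.frame(subject_id = asg$subject_id, visit = 1,
                               sc = y0), asg)
  i <- grepl("subtype", r0$term)
  expect_lt(abs(r0$estimate[i]), 2 * r0$se[i])

  # collinear covariate flagged unidentifiable
  asg2 <- asg
  asg2$age <- asg2$expected_stage * 2
  r2 <- score_model(scores, asg2)
  expect_true(any(r2$unidentifiable))
})

test_that("stage-EYO correlation behaves at its anchors", {
  asg <- data.frame(subject_id = sprintf("s%02d", 1:40), visit = 1,
                    label = rep(c("temporal", "frontotemporal"), 20),
                    expected_stage = seq(0.5, 20, length.out = 40))
  asg$eyo <- 2 * asg$expected_stage - 10
  r <- stage_eyo_correlation(asg)
  expect_equal(r$r[r$group == "overall"], 1, tolerance = 1e-12)

  set.seed(93)
  hits <- replicate(20, {
    asg$eyo <- rnorm(40)
    abs(stage_eyo_correlation(asg)$r[1]) < 0.3
  })
  expect_gte(mean(hits), 0.9)
  expect_error(stage_eyo_correlation(asg[1:2, ]), "at least 3")
})

test_that("rank comparisons cover ties, shifts, and extremes", {
  set.seed(94)
  # identical distributions: p approximately uniform across replicates
  ps <- replicate(300, rank_compare(rnorm(20), rnorm(20))$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)

  # a 1.5-SD location shift at n = 20 vs 20 is detected almost always
  hits <- replicate(50, rank_compare(rnorm(20), rnorm(20, 1.5))$p < 0.01)
  expect_gte(mean(hits), 0.9)

  # one group constant and strictly below the other: U = 0, minimal p
  r <- rank_compare(rep(1, 10), 2:11)
  expect_equal(unname(r$statistic), 0)
  expect_lt(r$p, 0.001)

  r2 <- rank_compare(rep(3, 8), rep(3, 9))
  expect_equal(r2$p, 1)
  expect_match(r2$note, "tied")
})

test_that("statistics are invariant to row order", {
  set.seed(95)
  df <- data.frame(g = sample(c("x", "y", "z"), 60, TRUE), v = rnorm(60))
  a <- compare_groups(df, "v", "g")
  b <- compare_groups(df[sample(60), ], "v", "g")
  expect_equal(a, b, tolerance = 1e-12)
})
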