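# Toy model used throughout: 2 biomarkers x 2 thresholds (E = 4), both
# "opposite" orderings as two subtypes.
toy4 <- function(f = c(0.5, 0.5), sigma = 1) {
  ev <- zscore_events(c("a", "b"), z_thresholds = c(1, 2), z_max = 5)
  toy_model(ev,
            list(c(1L, 2L, 3L, 4L),   # a1 a2 b1 b2
                 c(3L, 4L, 1L, 2L)),  # b1 b2 a1 a2
            f = f, sigma = sigma)
}

test_that("subject likelihood matches brute-force enumeration at E = 4", {
  m <- toy4()
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(2, sd = 2)
    names(x) <- c("a", "b")
    got <- subject_likelihood(x, m)
    want <- oracle_likelihood_table(m, x)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
    # stage-marginalised per-subtype log-likelihood
    Z <- matrix(x, 1, dimnames = list(NULL, c("a", "b")))
    for (c in 1:2) {
      expect_equal(sustainz:::seq_margll(m$events, m$sequences[[c]], Z, 1),
                   log(mean(want[c, ])), tolerance = 1e-10)
    }
  }
})

test_that("an all-zero profile is most likely at stage 0 under every subtype", {
  m <- toy4()
  L <- subject_likelihood(c(a = 0, b = 0), m)
  expect_equal(unname(apply(L, 1, which.max)), c(1L, 1L))
})

test_that("likelihood ratio between subtypes matches enumeration on-trajectory", {
  ev <- zscore_events(c("a", "b"), z_thresholds = list(a = 1, b = 1))
  m <- toy_model(ev, list(c(1L, 2L), c(2L, 1L)))
  # exactly subtype 1's stage-1 profile
  x <- setNames(stage_means(ev, m$sequences[[1]])[2, ], c("a", "b"))
  got <- subject_likelihood(x, m)
  want <- oracle_likelihood_table(m, x)
  r_got <- sum(got[1, ]) / sum(got[2, ])
  r_want <- sum(want[1, ]) / sum(want[2, ])
  expect_equal(r_got, r_want, tolerance = 1e-10)
  expect_gt(r_got, 1)
})

test_that("inflating sigma flattens the stage posterior", {
  ev <- zscore_events(c("a", "b"), z_thresholds = c(1, 2), z_max = 5)
  m1 <- toy_model(ev, list(c(1L, 2L, 3L, 4L)))
  x <- c(a = 1.7, b = 0.4)
  entropy <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  ents <- sapply(c(1, 1.5, 2, 3), function(sg) {
    m1$sigma <- sg
    L <- subject_likelihood(x, m1)
    p <- L[1, ] / sum(L[1, ])
    entropy(p)
  })
  expect_true(all(diff(ents) > 0))
})

test_that("missing or NA biomarkers are a hard error (no imputation)", {
  m <- toy4()
  expect_error(subject_likelihood(c(a = 1), m), "missing biomarker")
  expect_error(subject_likelihood(c(a = 1, b = NA), m), "NA")
})
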