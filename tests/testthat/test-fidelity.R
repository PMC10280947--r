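test_that("chi2_test equals the textbook statistic and is permutation invariant", {
  set.seed(1)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    got <- chi2_test(tab)
    # independent oracle: sum((O - E)^2 / E) with closed-form expecteds
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
    expect_equal(got$p,
                 pchisq(got$statistic, (nrow(tab) - 1) * (ncol(tab) - 1),
                        lower.tail = FALSE))
    perm <- tab[2:1, c(2, 3, 1)]
    expect_equal(chi2_test(perm)$p, got$p, tolerance = 1e-12)
  }
  expect_equal(chi2_test(matrix(c(10, 20, 10, 20), 2))$statistic, 0)
  expect_equal(chi2_test(matrix(c(10, 20, 10, 20), 2))$p, 1)
  expect_error(chi2_test(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
  expect_error(chi2_test(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("rank_sum_test agrees with exact enumeration on small samples", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_gte(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  # enumeration oracle over all choose(8, 4) = 70 rank assignments
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  r <- rank(c(x, y))
  obs <- sum(r[1:4])
  all_sums <- combn(8, 4, function(idx) sum(r[idx]))
  p_exact <- mean(abs(all_sums - 18) >= abs(obs - 18)) # 18 = null mean
  got <- rank_sum_test(x, y)$p
  expect_lt(abs(got - p_exact), 0.02)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("mean_test is a calibrated Welch test", {
  expect_equal(mean_test(1:10, 1:10), 1)
  expect_lt(mean_test(c(0, 0, 1, 1), c(10, 10, 11, 11)), 0.001)
  set.seed(2)
  rejections <- mean(replicate(1000, {
    mean_test(rnorm(50), rnorm(50)) < 0.05
  }))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
  expect_error(mean_test(1, 1:4), "two observations")
})

test_that("age_effect recovers the generating per-year multiplier", {
  spec <- default_spec()
  spec$n <- 2500L
  a <- sample_cohort(spec, seed = 1)
  b <- sample_cohort(spec, seed = 2)
  pooled <- pool_cohorts(a, b)
  pooled$source <- rep(c("real", "fake"), c(nrow(a), nrow(b)))
  res <- age_effect(pooled)
  expect_gt(res$or_per_year, 0.96)
  expect_lt(res$or_per_year, 0.98)
  expect_lt(res$age_p, 0.01)
  expect_gt(res$interaction_p, 0.05)
})

test_that("age_effect detects a null and a real source interaction", {
  spec <- default_spec()
  spec$n <- 2500L
  a <- sample_cohort(spec, seed = 3)
  shuffled <- a
  shuffled$age <- with_seed(4, sample(shuffled$age))
  b <- sample_cohort(spec, seed = 5)
  pooled <- pool_cohorts(shuffled, b)
  pooled$source <- rep(c("real", "fake"), each = 2500)
  null_fit <- glm(I(outcome == "more") ~ age, data = shuffled,
                  family = binomial())
  ci <- exp(confint.default(null_fit)["age", ])
  expect_true(ci[1] < 1 && ci[2] > 1)

  # deliberately different age effects across sources -> interaction
  spec_strong <- default_spec()
  spec_strong$n <- 2500L
  spec_strong$outcome_model["age"] <- log(0.90)
  spec_strong <- recalibrate(spec_strong)
  spec_null <- default_spec()
  spec_null$n <- 2500L
  spec_null$outcome_model["age"] <- 0
  spec_null <- recalibrate(spec_null)
  pooled2 <- pool_cohorts(sample_cohort(spec_strong, seed = 6),
                          sample_cohort(spec_null, seed = 7))
  pooled2$source <- rep(c("real", "fake"), each = 2500)
  expect_lt(age_effect(pooled2)$interaction_p, 0.01)
})

test_that("compare_cohorts reports nine rows and degenerates correctly", {
  co <- sample_cohort(default_spec(), seed = 9)
  rep_self <- suppressWarnings(compare_cohorts(co, co))
  expect_equal(nrow(rep_self), 9L)
  expect_true(all(rep_self$p >= 0.99))
  expect_equal(rep_self$variable,
               c("age", "gender", "ecog", "site", "bone_mets", "btcp",
                 "neuropathic", "med_gt60", "n_televisits"))
  other <- co
  names(other)[2] <- "years"
  expect_error(compare_cohorts(co, other), "schema")
})
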