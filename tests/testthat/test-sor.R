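# Analytic oracle classifiers: functions mapping records to P(more).
oracle_constant <- function(p) function(records) rep(p, nrow(records))
oracle_logistic <- function(beta, var, intercept = 0) {
  function(records) plogis(intercept + beta * records[[var]])
}

test_that("profile specifications validate their inputs", {
  expect_error(profile_spec(fixed = list(metastatic = 1)), "among")
  expect_error(profile_spec(fixed = list(age = 50),
                            age_gaussian = c(60, 5)), "both")
  expect_error(profile_spec(age_gaussian = c(60, -1)))
  p <- profile_spec(fixed = list(btcp = 1))
  expect_s3_class(p, "profile_spec")
})

test_that("condition presets mirror the published clinical conditions", {
  pre <- condition_presets()
  expect_length(pre, 4L)
  expect_named(pre, c("age", "btcp", "neuropathic", "btcp_neuro"))
  expect_equal(pre$age$target$age_gaussian, c(75, 5))
  expect_equal(pre$age$reference$age_gaussian, c(45, 5))
  expect_length(pre$age$target$fixed, 0L)
  expect_equal(pre$btcp$target$fixed$btcp, 1)
  expect_equal(pre$btcp$reference$fixed$btcp, 0)
  expect_equal(pre$btcp_neuro$target$fixed,
               list(btcp = 1, neuropathic = 1))
})

test_that("odds_of applies the boundary continuity correction", {
  expect_equal(odds_of(0.5), 1)
  expect_equal(odds_of(0.8), 4)
  expect_equal(odds_of(1, eps = 0.0025), (1 - 0.0025) / 0.0025)
  expect_equal(odds_of(1, eps = 0.0025), 399, tolerance = 1e-9)
  expect_equal(odds_of(0, eps = 0.0025), 0.0025 / (1 - 0.0025))
  expect_error(odds_of(1.2))
})

test_that("simulated risk matches the classifier it wraps", {
  prof <- profile_spec()
  expect_equal(simulate_profile(oracle_constant(1), prof, S = 50, seed = 1),
               1)
  expect_equal(simulate_profile(oracle_constant(0), prof, S = 50, seed = 1),
               0)
  # binomial oracle: constant P(more) = 0.7 -> mean risk ~ 0.7
  set.seed(2)
  risks <- replicate(500, simulate_profile(oracle_constant(0.7), prof,
                                           S = 200))
  expect_gt(mean(risks), 0.68)
  expect_lt(mean(risks), 0.72)
  expect_error(
    simulate_profile(function(records) rep(2, nrow(records)), prof,
                     S = 10, seed = 1),
    "invalid")
})

test_that("a null self-comparison centers on 1", {
  prof <- profile_spec(fixed = list(btcp = 1))
  model <- oracle_logistic(0.5, "btcp")
  res <- compute_sor(model, prof, prof, sor_config(seed = 3))
  expect_gt(res$mean, 0.8)
  expect_lt(res$mean, 1.25)
  expect_true(res$ci[1] <= 1 && res$ci[2] >= 1)
  expect_length(res$samples, 300L)
  expect_equal(res$ci, unname(quantile(res$samples, c(0.025, 0.975),
                                       type = 1)))
})

test_that("the sOR recovers a known binary log-odds effect", {
  model <- oracle_logistic(log(2), "btcp")
  res <- compute_sor(model,
                     profile_spec(fixed = list(btcp = 1)),
                     profile_spec(fixed = list(btcp = 0)),
                     sor_config(seed = 4))
  expect_gt(res$mean, 1.7)
  expect_lt(res$mean, 2.3)
})

test_that("swapping target and reference inverts the sOR", {
  model <- oracle_logistic(log(2), "btcp")
  t1 <- profile_spec(fixed = list(btcp = 1))
  t0 <- profile_spec(fixed = list(btcp = 0))
  a <- compute_sor(model, t1, t0, sor_config(seed = 5))
  b <- compute_sor(model, t0, t1, sor_config(seed = 5))
  expect_equal(a$mean, 1 / b$mean, tolerance = 0.15)
})

test_that("compute_sor is deterministic and validates free-feature laws", {
  model <- oracle_constant(0.6)
  t1 <- profile_spec(fixed = list(btcp = 1))
  t0 <- profile_spec(fixed = list(btcp = 0))
  a <- compute_sor(model, t1, t0, sor_config(S = 20, R = 20, seed = 6))
  b <- compute_sor(model, t1, t0, sor_config(S = 20, R = 20, seed = 6))
  expect_identical(a$samples, b$samples)
  t_uni <- profile_spec(fixed = list(btcp = 1), free_mode = "uniform")
  expect_error(compute_sor(model, t_uni, t0, sor_config(S = 5, R = 5)),
               "free-feature law")
})

test_that("a probability forest recovers encoded BTcP effects", {
  pre <- condition_presets()
  for (omega in c(1.5, 2)) {
    spec <- default_spec()
    spec$n <- 2000L
    spec$outcome_model["btcp"] <- log(omega)
    spec <- recalibrate(spec)
    co <- sample_cohort(spec, seed = round(100 * omega))
    m <- risk_model(co, seed = 7)
    res <- compute_sor(m, pre$btcp$target, pre$btcp$reference,
                       sor_config(seed = 8), spec)
    expect_gte(res$mean, 0.75 * omega)
    expect_lte(res$mean, 1.25 * omega)
  }
})

test_that("risk_by_age tracks monotone age effects", {
  flat <- risk_by_age(oracle_constant(0.4), ages = seq(20, 90, by = 10),
                      S = 100, seed = 9)
  expect_true(all(flat$risk >= 0 & flat$risk <= 1))
  expect_lt(diff(range(flat$risk)), 0.2)
  model <- oracle_logistic(-0.08, "age", intercept = 4)
  curve <- risk_by_age(model, ages = seq(20, 95, length.out = 20),
                       S = 500, seed = 10)
  rho <- cor(curve$age, curve$risk, method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("sor results serialize with their summary row", {
  res <- compute_sor(oracle_constant(0.5),
                     profile_spec(fixed = list(btcp = 1)),
                     profile_spec(fixed = list(btcp = 0)),
                     sor_config(S = 10, R = 10, seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_sor(res, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 11L)
  expect_equal(df$mean[11], res$mean)
})
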