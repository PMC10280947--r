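test_that("default calibration reproduces the published margins exactly", {
  spec <- default_spec()
  expect_equal(unname(spec$prevalences["btcp"]), (38 + 43) / 218)
  expect_equal(unname(spec$prevalences["neuropathic"]), (39 + 50) / 218)
  expect_equal(unname(spec$prevalences["med_gt60"]), (65 + 68) / 218)
  expect_equal(unname(spec$prevalences["metastatic"]), 0.906)
  expect_equal(unname(exp(spec$outcome_model["age"])), 0.97)
  expect_equal(spec$p_one, 108 / 218)
  expect_equal(spec$n, 218L)
  # per-gender site distributions are proper distributions honoring the
  # gender-consistency contract
  expect_equal(colSums(spec$site_table), c(female = 1, male = 1))
  expect_equal(spec$site_table["prostate", "female"], 0)
  expect_equal(spec$site_table["gynecological", "male"], 0)
})

test_that("the calibrated intercept hits the marginal outcome split", {
  spec <- default_spec()
  # exact expectation over the covariate distribution (independent oracle:
  # Monte-Carlo average of outcome_probability over a large sample)
  big <- spec
  big$n <- 50000L
  co <- sample_cohort(big, seed = 4)
  expect_equal(mean(co$outcome == "one"), spec$p_one, tolerance = 0.02)
})

test_that("outcome_probability follows the logistic closed form", {
  rec <- manual_cohort(45, "male", "lung")
  zero <- c(intercept = 0, age = 0, btcp = 0, neuropathic = 0,
            gender_male = 0, med_gt60 = 0, bone_mets = 0)
  expect_equal(outcome_probability(rec, zero), 0.5)
  m2 <- zero
  m2["intercept"] <- 2
  expect_equal(outcome_probability(rec, m2), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  # +1 year of age multiplies the odds by exactly exp(age coefficient)
  m3 <- zero
  m3["age"] <- log(0.97)
  rec2 <- manual_cohort(c(46, 45), "male", "lung")
  p <- outcome_probability(rec2, m3)
  odds <- p / (1 - p)
  expect_equal(odds[1] / odds[2], 0.97, tolerance = 1e-12)
  bad <- zero
  bad["age"] <- Inf
  expect_error(outcome_probability(rec, bad), "finite")
})

test_that("sample_cohort is deterministic, respects invariants and margins", {
  spec <- default_spec()
  a <- sample_cohort(spec, seed = 10)
  b <- sample_cohort(spec, seed = 10)
  expect_identical(a, b)
  expect_equal(nrow(a), 218L)
  # record-level invariants
  expect_true(all(a$bone_mets <= a$metastatic))
  expect_true(all((a$outcome == "more") == (a$n_televisits > 1)))
  expect_true(all(a$gender[a$site == "prostate"] == "male"))
  expect_true(all(a$gender[a$site == "gynecological"] == "female"))
  expect_true(all(a$n_televisits >= 1 & a$n_televisits <= spec$visit_max))
  expect_true(all(a$age >= 18 & a$age <= 95))
  # binomial 99% band at n = 218 around the calibrated BTcP margin
  expect_lt(abs(mean(a$btcp) - 0.372), 0.07)
  # tele-visit count distribution near the published moments (default seed)
  d <- sample_cohort(spec)
  expect_lt(abs(mean(d$n_televisits) - 2.1), 0.25)
  expect_equal(median(d$n_televisits[d$outcome == "more"]), 2)
  # degenerate sizes
  empty_spec <- spec
  empty_spec$n <- 0L
  expect_equal(nrow(sample_cohort(empty_spec, seed = 1)), 0L)
  neg <- spec
  neg$n <- -1L
  expect_error(sample_cohort(neg, seed = 1), "non-negative")
})

test_that("a large default cohort recovers the encoded per-year age effect", {
  spec <- default_spec()
  spec$n <- 5000L
  co <- sample_cohort(spec, seed = 42)
  fit <- glm(I(outcome == "more") ~ age, data = co, family = binomial())
  expect_gt(exp(coef(fit)["age"]), 0.96)
  expect_lt(exp(coef(fit)["age"]), 0.98)
})

test_that("summarize_cohort conserves counts and matches margins", {
  two <- manual_cohort(c(60, 60), "female", "breast")
  s <- summarize_cohort(two)
  expect_equal(unname(s$gender$counts["female", "one"]), 2)
  expect_equal(unname(s$gender$pct["female", "one"]), 100)
  co <- sample_cohort(default_spec(), seed = 5)
  s2 <- summarize_cohort(co)
  # column sums equal group sizes for every categorical variable
  for (v in c("gender", "site", "bone_mets", "btcp", "neuropathic",
              "med_gt60")) {
    expect_equal(colSums(s2[[v]]$counts), s2$n, ignore_attr = TRUE)
    expect_equal(colSums(s2[[v]]$pct), c(100, 100), ignore_attr = TRUE,
                 tolerance = 1e-3)
  }
  met <- sum(s2$bone_mets$counts) # just conservation of total n
  expect_equal(sum(s2$n), nrow(co))
  expect_lt(abs(mean(co$metastatic) - 0.906), 0.05)
  expect_error(summarize_cohort(small_cohort(0)), "empty")
})

test_that("cohort and spec serialization round-trip", {
  spec <- default_spec()
  f <- withr::local_tempfile(fileext = ".json")
  write_spec(spec, f)
  spec2 <- read_spec(f)
  expect_equal(spec2$outcome_model, spec$outcome_model)
  expect_equal(spec2$site_table, spec$site_table)
  expect_equal(sample_cohort(spec2, seed = 3), sample_cohort(spec, seed = 3))

  co <- sample_cohort(spec, seed = 8)
  g <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, g)
  hdr <- readLines(g, n = 1)
  expect_equal(hdr, paste0('"patient_id","age","gender","site",',
                           '"metastatic","bone_mets","btcp","neuropathic",',
                           '"ecog","med_gt60","n_televisits","outcome"'))
  co2 <- read_cohort(g)
  expect_equal(as.data.frame(co2), as.data.frame(co))
})
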