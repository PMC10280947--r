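#' Calibration of the synthetic tele-pain cohort
#'
#' A `cohort_spec` bundles every parameter of the synthetic data-generating
#' process: sample size, gender split, (truncated-Gaussian) age margin,
#' per-gender tumor-site table, prevalences of the binary clinical features,
#' the ECOG performance-status distribution, the logistic outcome model for
#' "more than one tele-visit", and the tele-visit count distribution given
#' the outcome.
#'
#' `default_spec()` returns the calibration whose implied margins match the
#' published real-data cohort of 218 cancer-pain patients: breakthrough
#' cancer pain (BTcP) prevalence 81/218 (37.2%), neuropathic pain 89/218
#' (40.8%), morphine-equivalent dose (MED) > 60 mg 133/218 (61%), bone
#' metastases 99/218, metastatic disease 90.6%, a per-year age odds
#' multiplier of 0.97 on the odds of more than one tele-visit, and a
#' marginal probability of exactly one tele-visit of 108/218 (49.5%).
#' The logistic intercept is solved numerically (exact expectation over the
#' discretized age margin and the 2^5 binary covariate patterns) so that
#' the marginal outcome split is reproduced by construction.
#'
#' @return an object of class `cohort_spec`.
#' @seealso [sample_cohort()], [outcome_probability()]
#' @export
default_spec <- function() {
  sites <- site_levels()
  # Real-data site totals (one + more tele-visit columns).
  tot <- c(bladder = 16, breast = 30, gastrointestinal = 42,
           gynecological = 9, `head&neck` = 14, kidney = 6, lung = 31,
           `melanoma/skin` = 5, pancreas = 10, prostate = 14,
           `soft tissue&bones` = 22, other = 19)
  stopifnot(sum(tot) == 218, identical(names(tot), sites))

  # Per-gender table honoring the gender-consistency contract:
  # prostate male-only, gynecological female-only, breast >= 95% female;
  # gender-neutral sites share the remaining mass proportionally.
  n_f <- 114; n_m <- 104
  f <- setNames(numeric(12), sites)
  m <- setNames(numeric(12), sites)
  f["gynecological"] <- 9
  m["prostate"] <- 14
  f["breast"] <- 0.95 * 30
  m["breast"] <- 0.05 * 30
  neutral <- setdiff(sites, c("gynecological", "prostate", "breast"))
  frac_f <- (n_f - sum(f)) / sum(tot[neutral])
  f[neutral] <- tot[neutral] * frac_f
  m[neutral] <- tot[neutral] * (1 - frac_f)
  site_table <- cbind(female = f / sum(f), male = m / sum(m))

  # Log-odds effects implied by the real-data one-vs-more cross tables.
  outcome_model <- c(
    intercept   = NA_real_,
    age         = log(0.97),                 # -3% odds per year of age
    btcp        = log((43 * 70) / (38 * 67)),
    neuropathic = log((50 * 69) / (39 * 60)),
    gender_male = log((45 * 49) / (59 * 65)),
    med_gt60    = log((68 * 43) / (65 * 42)),
    bone_mets   = log((49 * 58) / (50 * 61))
  )

  spec <- structure(list(
    n = 218L,
    gender_split = 114 / 218,          # probability of female
    age_mean = 64, age_sd = 12, age_min = 18L, age_max = 95L,
    site_table = site_table,
    prevalences = c(btcp = 81 / 218, neuropathic = 89 / 218,
                    med_gt60 = 133 / 218, bone_mets = 99 / 218,
                    metastatic = 0.906),
    ecog_dist = c(`0` = 0.05, `1` = 0.15, `2` = 0.35, `3` = 0.30,
                  `4` = 0.15),
    outcome_model = outcome_model,
    p_one = 108 / 218,                 # target marginal P(one tele-visit)
    visit_geom_p = 0.55, visit_max = 8L,
    seed = 20230620L
  ), class = "cohort_spec")
  spec$outcome_model["intercept"] <- calibrate_intercept(spec)
  validate_spec(spec)
  spec
}

#' Solve the logistic intercept for a target marginal outcome split
#'
#' Computes the intercept so that the expected probability of "more than one
#' tele-visit" over the spec's covariate distribution equals `1 - spec$p_one`.
#' The expectation is exact: the (rounded, truncated Gaussian) age margin is
#' enumerated on the integer grid and crossed with all 2^5 binary covariate
#' patterns and the two genders.
#'
#' @param spec a `cohort_spec` (its `intercept` entry is ignored).
#' @return the calibrated intercept (numeric scalar).
#' @keywords internal
calibrate_intercept <- function(spec) {
  ages <- spec$age_min:spec$age_max
  wa <- age_pmf(spec)
  bm <- spec$outcome_model
  pv <- spec$prevalences
  combos <- expand.grid(btcp = 0:1, neuropathic = 0:1, male = 0:1,
                        med_gt60 = 0:1, bone_mets = 0:1)
  pmale <- 1 - spec$gender_split
  wcombo <- with(combos,
    ifelse(btcp == 1, pv["btcp"], 1 - pv["btcp"]) *
    ifelse(neuropathic == 1, pv["neuropathic"], 1 - pv["neuropathic"]) *
    ifelse(male == 1, pmale, 1 - pmale) *
    ifelse(med_gt60 == 1, pv["med_gt60"], 1 - pv["med_gt60"]) *
    ifelse(bone_mets == 1, pv["bone_mets"], 1 - pv["bone_mets"]))
  lp0 <- as.matrix(combos) %*%
    bm[c("btcp", "neuropathic", "gender_male", "med_gt60", "bone_mets")]
  target <- 1 - spec$p_one
  f <- function(b0) {
    # E[plogis(b0 + b_age*age + lp0)] - target
    p <- outer(drop(lp0), bm["age"] * ages, `+`) + b0
    sum(wcombo * (plogis(p) %*% wa)) - target
  }
  uniroot(f, c(-20, 20), tol = 1e-10)$root
}

# pmf of the rounded truncated-Gaussian age margin on the integer grid
age_pmf <- function(spec) {
  ages <- spec$age_min:spec$age_max
  w <- pnorm(pmin(ages + 0.5, spec$age_max), spec$age_mean, spec$age_sd) -
       pnorm(pmax(ages - 0.5, spec$age_min), spec$age_mean, spec$age_sd)
  w / sum(w)
}

#' Validate a cohort specification
#'
#' Checks all structural invariants: probabilities in \[0,1\], the site
#' table and ECOG distribution summing to one (within 1e-9), finite outcome
#' coefficients, positive age SD and a non-negative sample size.
#'
#' @param spec a `cohort_spec`.
#' @return `spec`, invisibly; stops with a message on violation.
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n < 0) stop("spec$n must be non-negative")
  probs <- c(spec$gender_split, spec$prevalences, spec$p_one,
             spec$visit_geom_p, as.vector(spec$site_table), spec$ecog_dist)
  if (any(probs < -1e-12 | probs > 1 + 1e-12)) {
    stop("all probabilities in a cohort_spec must lie in [0, 1]")
  }
  if (any(abs(colSums(spec$site_table) - 1) > 1e-9)) {
    stop("per-gender site distributions must sum to 1")
  }
  if (abs(sum(spec$ecog_dist) - 1) > 1e-9) {
    stop("ecog_dist must sum to 1")
  }
  if (!all(is.finite(spec$outcome_model))) {
    stop("outcome model coefficients must be finite")
  }
  if (spec$age_sd <= 0) stop("age_sd must be positive")
  if (spec$prevalences["bone_mets"] > spec$prevalences["metastatic"] + 1e-12) {
    stop("bone metastasis prevalence cannot exceed metastatic prevalence")
  }
  invisible(spec)
}

#' Recalibrate a modified specification
#'
#' After changing outcome-model coefficients or prevalences, re-solves the
#' intercept so the marginal outcome split `p_one` is preserved.
#'
#' @param spec a `cohort_spec`.
#' @return the spec with an updated intercept.
#' @export
recalibrate <- function(spec) {
  spec$outcome_model["intercept"] <- calibrate_intercept(spec)
  validate_spec(spec)
  spec
}

#' @exportS3Method
print.cohort_spec <- function(x, ...) {
  cat("Synthetic tele-pain cohort specification\n")
  cat(sprintf("  n = %d, P(female) = %.3f, age ~ round(TN(%g, %g, [%d, %d]))\n",
              x$n, x$gender_split, x$age_mean, x$age_sd, x$age_min, x$age_max))
  cat(sprintf("  prevalences: %s\n",
              paste(sprintf("%s=%.3f", names(x$prevalences), x$prevalences),
                    collapse = ", ")))
  cat(sprintf("  P(one tele-visit) = %.3f; per-year age odds multiplier = %.3f\n",
              x$p_one, exp(x$outcome_model["age"])))
  cat("  outcome log-odds effects:\n")
  print(round(x$outcome_model, 4))
  invisible(x)
}

#' Serialize / deserialize a cohort specification as JSON
#'
#' @param spec a `cohort_spec`.
#' @param path file path.
#' @return `read_spec` returns a `cohort_spec`; `write_spec` returns `path`
#'   invisibly.
#' @export
write_spec <- function(spec, path) {
  validate_spec(spec)
  obj <- unclass(spec)
  obj$site_table <- list(levels = rownames(spec$site_table),
                         female = unname(spec$site_table[, "female"]),
                         male = unname(spec$site_table[, "male"]))
  # named vectors must become JSON objects, not bare arrays
  for (nm in c("prevalences", "ecog_dist", "outcome_model")) {
    obj[[nm]] <- as.list(obj[[nm]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  st <- cbind(female = obj$site_table$female, male = obj$site_table$male)
  rownames(st) <- obj$site_table$levels
  obj$site_table <- st
  for (nm in c("prevalences", "ecog_dist", "outcome_model")) {
    obj[[nm]] <- unlist(obj[[nm]])
  }
  obj$n <- as.integer(obj$n)
  spec <- structure(obj, class = "cohort_spec")
  validate_spec(spec)
  spec
}
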