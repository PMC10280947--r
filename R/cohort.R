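#' Probability of more than one tele-visit for given patient records
#'
#' Evaluates the logistic outcome model on one or more patient records:
#' `logit P(more) = intercept + b_age*age + b_btcp*btcp + b_neuro*neuropathic
#' + b_male*[gender == male] + b_med*med_gt60 + b_bone*bone_mets`.
#' The odds ratio between two records differing by one year of age is
#' `exp(b_age)`; the default calibration uses `b_age = log(0.97)`, the
#' published 3% per-year decrease in the odds of a repeat tele-visit.
#'
#' @param record a data frame with columns `age`, `gender`, `btcp`,
#'   `neuropathic`, `med_gt60`, `bone_mets` (one row per patient).
#' @param model named coefficient vector as in `cohort_spec$outcome_model`.
#' @return vector of probabilities of outcome "more".
#' @export
outcome_probability <- function(record, model) {
  if (!all(is.finite(model))) stop("outcome model coefficients must be finite")
  male <- as.integer(as.character(record$gender) == "male")
  lp <- model["intercept"] +
    model["age"] * record$age +
    model["btcp"] * record$btcp +
    model["neuropathic"] * record$neuropathic +
    model["gender_male"] * male +
    model["med_gt60"] * record$med_gt60 +
    model["bone_mets"] * record$bone_mets
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  unname(plogis(lp))
}

#' Sample a synthetic patient cohort
#'
#' Draws `spec$n` patient records from the data-generating process described
#' by a [cohort_spec][default_spec]: gender, tumor site conditional on
#' gender (so prostate is male-only, gynecological female-only and breast
#' at least 95% female), rounded truncated-Gaussian age, metastatic status
#' with bone metastases nested inside it, independent BTcP / neuropathic /
#' MED>60 indicators, ECOG 0-4, the outcome drawn from
#' [outcome_probability()], and the tele-visit count: 1 for outcome "one",
#' `2 + Geometric(p)` capped at `visit_max` for outcome "more".
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed; identical seed and spec give a bit-identical
#'   cohort. Defaults to `spec$seed`.
#' @return a `patient_cohort` data frame with columns `patient_id`, `age`,
#'   `gender`, `site`, `metastatic`, `bone_mets`, `btcp`, `neuropathic`,
#'   `ecog`, `med_gt60`, `n_televisits`, `outcome`.
#' @export
sample_cohort <- function(spec, seed = spec$seed) {
  validate_spec(spec)
  n <- spec$n
  if (n == 0) return(empty_cohort())
  with_seed(seed, {
    gender <- factor(ifelse(runif(n) < spec$gender_split, "female", "male"),
                     levels = gender_levels())
    site <- character(n)
    for (g in gender_levels()) {
      idx <- which(gender == g)
      if (length(idx)) {
        site[idx] <- sample(rownames(spec$site_table), length(idx),
                            replace = TRUE, prob = spec$site_table[, g])
      }
    }
    site <- factor(site, levels = site_levels())
    # rounded truncated-Gaussian age via inverse CDF
    lo <- pnorm(spec$age_min, spec$age_mean, spec$age_sd)
    hi <- pnorm(spec$age_max, spec$age_mean, spec$age_sd)
    age <- as.integer(round(qnorm(runif(n, lo, hi), spec$age_mean,
                                  spec$age_sd)))
    age <- pmin(pmax(age, spec$age_min), spec$age_max)
    pv <- spec$prevalences
    metastatic <- rbinom(n, 1, pv["metastatic"])
    p_bone_given_met <- min(1, pv["bone_mets"] / pv["metastatic"])
    bone_mets <- metastatic * rbinom(n, 1, p_bone_given_met)
    btcp <- rbinom(n, 1, pv["btcp"])
    neuropathic <- rbinom(n, 1, pv["neuropathic"])
    med_gt60 <- rbinom(n, 1, pv["med_gt60"])
    ecog <- as.integer(sample(0:4, n, replace = TRUE, prob = spec$ecog_dist))
    rec <- data.frame(age = age, gender = gender, btcp = btcp,
                      neuropathic = neuropathic, med_gt60 = med_gt60,
                      bone_mets = bone_mets)
    p_more <- outcome_probability(rec, spec$outcome_model)
    more <- rbinom(n, 1, p_more)
    n_tv <- ifelse(more == 1,
                   pmin(2L + rgeom(n, spec$visit_geom_p), spec$visit_max),
                   1L)
    cohort <- data.frame(
      patient_id = seq_len(n), age = age, gender = gender, site = site,
      metastatic = metastatic, bone_mets = bone_mets, btcp = btcp,
      neuropathic = neuropathic, ecog = ecog, med_gt60 = med_gt60,
      n_televisits = as.integer(n_tv),
      outcome = factor(ifelse(more == 1, "more", "one"),
                       levels = outcome_levels())
    )
    class(cohort) <- c("patient_cohort", "data.frame")
    cohort
  })
}

empty_cohort <- function() {
  cohort <- data.frame(
    patient_id = integer(0), age = integer(0),
    gender = factor(character(0), levels = gender_levels()),
    site = factor(character(0), levels = site_levels()),
    metastatic = integer(0), bone_mets = integer(0), btcp = integer(0),
    neuropathic = integer(0), ecog = integer(0), med_gt60 = integer(0),
    n_televisits = integer(0),
    outcome = factor(character(0), levels = outcome_levels())
  )
  class(cohort) <- c("patient_cohort", "data.frame")
  cohort
}

cohort_columns <- function() {
  c("patient_id", "age", "gender", "site", "metastatic", "bone_mets",
    "btcp", "neuropathic", "ecog", "med_gt60", "n_televisits", "outcome")
}

# coerce a plain data frame (e.g. read from CSV) into the cohort schema
as_patient_cohort <- function(df) {
  stopifnot(all(cohort_columns() %in% names(df)))
  df <- df[, cohort_columns()]
  df$gender <- factor(as.character(df$gender), levels = gender_levels())
  df$site <- factor(as.character(df$site), levels = site_levels())
  df$outcome <- factor(as.character(df$outcome), levels = outcome_levels())
  for (v in c("patient_id", "age", "metastatic", "bone_mets", "btcp",
              "neuropathic", "ecog", "med_gt60", "n_televisits")) {
    df[[v]] <- as.integer(df[[v]])
  }
  if (any(is.na(df$gender)) || any(is.na(df$site)) || any(is.na(df$outcome)))
    stop("unknown gender/site/outcome level in cohort data")
  if (any((df$outcome == "more") != (df$n_televisits > 1)))
    stop("outcome must equal the dichotomized tele-visit count")
  class(df) <- c("patient_cohort", "data.frame")
  df
}

#' Write / read a patient cohort as CSV
#'
#' One row per patient with the fixed header `patient_id,age,gender,site,`
#' `metastatic,bone_mets,btcp,neuropathic,ecog,med_gt60,n_televisits,outcome`;
#' booleans as 0/1, outcome as `one`/`more`.
#'
#' @param cohort a `patient_cohort`.
#' @param path file path.
#' @return `read_cohort` returns a `patient_cohort`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort)[, cohort_columns()], path,
            row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  as_patient_cohort(read.csv(path, stringsAsFactors = FALSE))
}

#' Tabulate a cohort per outcome group
#'
#' Builds a two-column (one vs more tele-visits) descriptive table:
#' counts and percentages per level for categorical variables, mean/SD and
#' median/IQR for numeric ones — the layout used for univariate cohort
#' comparisons.
#'
#' @param cohort a non-empty `patient_cohort`.
#' @return a `cohort_summary` object: a list with per-variable tables and
#'   the group sizes.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop("cannot summarize an empty cohort")
  groups <- split(seq_len(nrow(cohort)), cohort$outcome)
  num_vars <- c("age", "ecog", "n_televisits")
  cat_vars <- list(gender = gender_levels(), site = site_levels(),
                   bone_mets = c("0", "1"), btcp = c("0", "1"),
                   neuropathic = c("0", "1"), med_gt60 = c("0", "1"))
  out <- list(n = vapply(groups, length, integer(1)))
  for (v in num_vars) {
    out[[v]] <- t(vapply(groups, function(idx) {
      x <- cohort[[v]][idx]
      c(mean = mean(x), sd = sd(x), median = median(x),
        q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)))
    }, numeric(5)))
  }
  for (v in names(cat_vars)) {
    lev <- cat_vars[[v]]
    counts <- vapply(groups, function(idx) {
      table(factor(as.character(cohort[[v]][idx]), levels = lev))
    }, numeric(length(lev)))
    counts <- matrix(counts, nrow = length(lev),
                     dimnames = list(lev, names(groups)))
    pct <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 100
    out[[v]] <- list(counts = counts, pct = pct)
  }
  structure(out, class = "cohort_summary")
}

#' @exportS3Method
print.cohort_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Cohort summary: one = %d, more = %d (n = %d)\n",
              x$n["one"], x$n["more"], sum(x$n)))
  for (v in c("age", "ecog", "n_televisits")) {
    m <- x[[v]]
    cat(sprintf("  %-13s mean (SD): %s | median (IQR): %s\n", v,
                paste(sprintf("%.0f (%.0f)", m[, "mean"], m[, "sd"]),
                      collapse = " / "),
                paste(sprintf("%.0f (%.0f, %.0f)", m[, "median"],
                              m[, "q1"], m[, "q3"]), collapse = " / ")))
  }
  for (v in c("gender", "site", "bone_mets", "btcp", "neuropathic",
              "med_gt60")) {
    cat(sprintf("  %s:\n", v))
    tab <- x[[v]]
    for (lev in rownames(tab$counts)) {
      cat(sprintf("    %-18s %3.0f (%4.*f%%) | %3.0f (%4.*f%%)\n", lev,
                  tab$counts[lev, "one"], digits, tab$pct[lev, "one"],
                  tab$counts[lev, "more"], digits, tab$pct[lev, "more"]))
    }
  }
  invisible(x)
}

#' @exportS3Method
summary.patient_cohort <- function(object, ...) summarize_cohort(object)

#' @exportS3Method
print.patient_cohort <- function(x, ...) {
  cat(sprintf("Patient cohort: %d records (%d one / %d more tele-visits)\n",
              nrow(x), sum(x$outcome == "one"), sum(x$outcome == "more")))
  if (nrow(x)) print(head(as.data.frame(x), 6))
  invisible(x)
}
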