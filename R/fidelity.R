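#' Pearson chi-squared test on a contingency table of counts
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` without Yates continuity
#' correction (the correction is deliberately off: two-level tables of
#' moderate size are compared on the uncorrected scale throughout).
#' Columns or rows with an all-zero margin are an error.
#'
#' @param table a matrix of non-negative integer counts (2 x k or r x c).
#' @return list with `statistic`, `df` and `p`.
#' @export
chi2_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("chi2_test needs non-negative integer counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi2_test: zero row or column margin")
  }
  ht <- chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test. For cohort-sized samples the normal approximation with
#' tie correction is used; for tiny samples (at most 12 observations in
#' total, where the approximation is visibly inaccurate under ties) the
#' exact permutation distribution of the rank sum is enumerated instead.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `statistic` (the Mann-Whitney U of `x`), `p` and the
#'   `method` used (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("rank_sum_test needs two non-empty samples")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 12) {
    # exact two-sided permutation p under the symmetric null of the rank sum
    w_obs <- sum(r[seq_len(n1)])
    mu <- n1 * (n1 + n2 + 1) / 2
    all_w <- utils::combn(n1 + n2, n1, function(idx) sum(r[idx]))
    p <- mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9)
    return(list(statistic = u, p = p, method = "exact"))
  }
  ht <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       method = "normal")
}

#' Welch two-sample t-test p-value
#'
#' @param x,y numeric samples with at least two observations each.
#' @return the two-sided p-value.
#' @export
mean_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("mean_test needs at least two observations per sample")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(1)
    stop("mean_test: both samples degenerate with different means")
  }
  unname(t.test(x, y)$p.value)
}

#' Per-year age effect on repeat tele-visits, pooled across data sources
#'
#' Fits `outcome ~ age * source` by logistic regression on a pooled cohort
#' carrying a real/generated indicator, and reports the per-year odds
#' multiplier `exp(b_age)` together with the Wald p-value of the
#' age-by-source interaction (a non-significant interaction means the age
#' effect does not differ between real and generated records).
#'
#' @param cohort a `patient_cohort`-like data frame with an additional
#'   `source` column (factor with two levels, e.g. real/fake).
#' @return list with `or_per_year`, `or_ci` (Wald 95%), `age_p`,
#'   `interaction_p` and the fitted `model`.
#' @export
age_effect <- function(cohort) {
  if (!"source" %in% names(cohort)) {
    stop("age_effect needs a 'source' column on the pooled cohort")
  }
  src <- factor(as.character(cohort$source))
  if (nlevels(src) != 2) stop("age_effect needs exactly two sources")
  y <- as.integer(cohort$outcome == "more")
  fit <- glm(y ~ age * source,
             data = data.frame(y = y, age = cohort$age, source = src),
             family = binomial())
  if (!fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE)) {
    stop(paste("logistic fit did not converge cleanly (possible",
               "separation); check that both outcomes occur across the",
               "age range in both sources"))
  }
  sm <- summary(fit)$coefficients
  b_age <- sm["age", ]
  int_row <- grep(":", rownames(sm), value = TRUE)
  list(or_per_year = unname(exp(b_age["Estimate"])),
       or_ci = unname(exp(b_age["Estimate"] +
                            c(-1.96, 1.96) * b_age["Std. Error"])),
       age_p = unname(b_age["Pr(>|z|)"]),
       interaction_p = unname(sm[int_row, "Pr(>|z|)"]),
       model = fit)
}

#' Univariate real-vs-generated cohort comparison
#'
#' One row per variable: categorical variables (gender, site, bone
#' metastases, BTcP, neuropathic pain, MED class) are compared with the
#' Pearson chi-squared test on the source-by-level table (levels absent
#' from both cohorts are dropped); numeric variables use the Welch t-test
#' for age and the tele-visit count and the Wilcoxon rank-sum test for
#' ECOG, with the other test's p-value also recorded.
#'
#' @param real,fake two `patient_cohort`s with identical schema.
#' @return a `fidelity_report`: data frame with columns `variable`, `type`,
#'   `test`, `statistic`, `p`, `p_t`, `p_wilcoxon`, plus the two cohort
#'   summaries as attributes.
#' @export
compare_cohorts <- function(real, fake) {
  if (!identical(sort(names(real)), sort(names(fake)))) {
    stop("real and fake cohorts must share the same schema")
  }
  num_primary <- c(age = "t", ecog = "wilcoxon", n_televisits = "t")
  cat_vars <- c("gender", "site", "bone_mets", "btcp", "neuropathic",
                "med_gt60")
  rows <- list()
  for (v in c("age", "gender", "ecog", "site", "bone_mets", "btcp",
              "neuropathic", "med_gt60", "n_televisits")) {
    if (v %in% cat_vars) {
      tab <- source_table(real[[v]], fake[[v]])
      ht <- chi2_test(tab)
      rows[[v]] <- data.frame(variable = v, type = "categorical",
                              test = "chi-squared",
                              statistic = ht$statistic, p = ht$p,
                              p_t = NA_real_, p_wilcoxon = NA_real_)
    } else {
      p_t <- mean_test(real[[v]], fake[[v]])
      rs <- rank_sum_test(real[[v]], fake[[v]])
      primary <- num_primary[[v]]
      rows[[v]] <- data.frame(
        variable = v, type = "numeric",
        test = if (primary == "t") "Welch t" else "Wilcoxon rank-sum",
        statistic = if (primary == "t") NA_real_ else rs$statistic,
        p = if (primary == "t") p_t else rs$p,
        p_t = p_t, p_wilcoxon = rs$p)
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "summary_real") <- summarize_cohort(real)
  attr(report, "summary_fake") <- summarize_cohort(fake)
  class(report) <- c("fidelity_report", "data.frame")
  report
}

levels_union <- function(a, b) union(unique(as.character(a)),
                                     unique(as.character(b)))

# 2 x k source-by-level count table, dropping all-zero levels
source_table <- function(a, b) {
  lev <- sort(levels_union(a, b))
  tab <- rbind(real = table(factor(as.character(a), levels = lev)),
               fake = table(factor(as.character(b), levels = lev)))
  tab[, colSums(tab) > 0, drop = FALSE]
}

#' @exportS3Method
print.fidelity_report <- function(x, ...) {
  cat("Univariate real-vs-generated comparison\n")
  df <- as.data.frame(x)
  df$statistic <- round(df$statistic, 2)
  for (col in c("p", "p_t", "p_wilcoxon")) df[[col]] <- signif(df[[col]], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a fidelity report as CSV
#'
#' @param report a `fidelity_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fidelity_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
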