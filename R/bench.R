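#' Design matrix and outcome vector for the classifier bench
#'
#' The outcome is the dichotomized tele-visit count (`one` vs `more`); the
#' predictors are age and ECOG (numeric) plus treatment-coded dummies for
#' gender, tumor site (11 columns), bone metastases, BTcP, neuropathic pain
#' and MED class — 18 columns in total. Metastatic status is deliberately
#' excluded: at ~90% prevalence it carries almost no information and is
#' dropped from the predictive feature set.
#'
#' @param cohort a `patient_cohort`.
#' @return list with `x` (numeric design matrix) and `y` (outcome factor).
#' @export
features <- function(cohort) {
  list(x = features_design(cohort),
       y = factor(as.character(cohort$outcome), levels = outcome_levels()))
}

# design matrix only; works on profile frames without outcome columns
features_design <- function(df) {
  d <- data.frame(
    age = as.numeric(df$age),
    ecog = as.numeric(df$ecog),
    gender = factor(as.character(df$gender), levels = gender_levels()),
    site = factor(as.character(df$site), levels = site_levels()),
    bone_mets = as.numeric(df$bone_mets),
    btcp = as.numeric(df$btcp),
    neuropathic = as.numeric(df$neuropathic),
    med_gt60 = as.numeric(df$med_gt60)
  )
  x <- model.matrix(~ age + ecog + gender + site + bone_mets + btcp +
                      neuropathic + med_gt60, d)
  x[, -1, drop = FALSE]
}

#' Classifier specifications with published default hyperparameters
#'
#' The four bench classifiers and their fixed configurations: elastic net
#' (kept under its published label "LASSO" although the mixing parameter
#' alpha = 0 is pure ridge) with shrinkage lambda = 0.25; random forest
#' with 13 candidate variables per split; gradient boosting with 100 trees,
#' maximum depth 5, shrinkage 0.1 and minimum 15 observations per leaf;
#' and a single-hidden-layer neural network with 10 units and weight decay
#' 0.035. The grid may hold several rows for tuning; rows are ordered from
#' simpler to more complex so cross-validation ties resolve toward the
#' simpler model.
#'
#' @param kind one of `"elastic"`, `"rf"`, `"gbm"`, `"ann"`.
#' @param grid optional data frame of hyperparameter rows overriding the
#'   one-point default grid.
#' @return a `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("elastic", "rf", "gbm", "ann"),
                            grid = NULL) {
  kind <- match.arg(kind)
  default <- switch(kind,
    elastic = data.frame(alpha = 0, lambda = 0.25),
    rf = data.frame(mtry = 13),
    gbm = data.frame(nrounds = 100, max_depth = 5, eta = 0.1,
                     min_child_weight = 15),
    ann = data.frame(size = 10, decay = 0.035))
  label <- switch(kind, elastic = "LASSO", rf = "RF", gbm = "GBM",
                  ann = "ANN")
  if (is.null(grid)) grid <- default
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  structure(list(kind = kind, label = label, grid = grid),
            class = "classifier_spec")
}

fit_inner <- function(kind, x, y, params, seed) {
  y01 <- as.integer(y == "more")
  with_seed(seed, switch(kind,
    elastic = glmnet::glmnet(x, y, family = "binomial",
                             alpha = params$alpha, lambda = params$lambda),
    rf = randomForest::randomForest(x = x, y = y,
                                    mtry = min(params$mtry, ncol(x))),
    gbm = xgboost::xgboost(
      data = x, label = y01, nrounds = params$nrounds,
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    min_child_weight = params$min_child_weight,
                    nthread = 1),
      verbose = 0),
    ann = nnet::nnet(x = x, y = y01, size = params$size,
                     decay = params$decay, entropy = TRUE, maxit = 500,
                     trace = FALSE)))
}

predict_inner <- function(kind, fit, x, params) {
  switch(kind,
    elastic = drop(predict(fit, x, s = params$lambda, type = "response")),
    rf = unname(predict(fit, x, type = "prob")[, "more"]),
    rf_prob = unname(predict(fit, data = x, num.threads = 1,
                             verbose = FALSE)$predictions[, "more"]),
    gbm = predict(fit, x),
    ann = drop(predict(fit, x)))
}

#' Tune a classifier by repeated stratified cross-validation
#'
#' For every grid row, computes the mean accuracy over `repeats`
#' repetitions of stratified K-fold cross-validation on the training
#' cohort, selects the row with the best mean accuracy (ties resolve to
#' the earlier = simpler row), and refits it on the full training set.
#' The two numeric predictors are standardized with training-set
#' parameters only, which are stored in the model and reapplied at
#' prediction time.
#'
#' @param spec a [classifier_spec()] (or a kind string).
#' @param train a `patient_cohort` used for tuning and the final fit.
#' @param k folds (>= 2); `repeats` repetitions.
#' @param repeats number of cross-validation repetitions.
#' @param seed integer seed; the same seed reproduces the selection and fit
#'   exactly.
#' @return a `telepain_model`: kind, label, chosen `params`, the fitted
#'   inner model, standardization parameters, the per-row CV table and the
#'   training accuracy.
#' @export
tune_classifier <- function(spec, train, k = 5, repeats = 3, seed = 1L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"), k >= 2)
  f <- features(train)
  if (min(table(f$y)) < k) stop("training set cannot be stratified into k folds")
  std <- list(center = c(age = mean(f$x[, "age"]), ecog = mean(f$x[, "ecog"])),
              scale = c(age = sd(f$x[, "age"]), ecog = sd(f$x[, "ecog"])))
  std$scale[std$scale == 0] <- 1
  x <- apply_standardization(f$x, std)
  y <- f$y

  folds <- with_seed(seed, lapply(seq_len(repeats), function(r) {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }))

  cv_acc <- numeric(nrow(spec$grid))
  for (g in seq_len(nrow(spec$grid))) {
    params <- spec$grid[g, , drop = FALSE]
    accs <- numeric(0)
    for (r in seq_len(repeats)) {
      for (fo in seq_len(k)) {
        tr <- folds[[r]] != fo
        fit <- fit_inner(spec$kind, x[tr, , drop = FALSE], y[tr], params,
                         seed = seed + 1000L * r + fo)
        p <- predict_inner(spec$kind, fit, x[!tr, , drop = FALSE], params)
        accs <- c(accs, mean((p > 0.5) == (y[!tr] == "more")))
      }
    }
    cv_acc[g] <- mean(accs)
  }
  best <- which.max(cv_acc)  # ties resolve to the earlier (simpler) row
  params <- spec$grid[best, , drop = FALSE]
  fit <- fit_inner(spec$kind, x, y, params, seed = seed)
  p_tr <- predict_inner(spec$kind, fit, x, params)
  structure(list(kind = spec$kind, label = spec$label, params = params,
                 fit = fit, std = std,
                 cv = cbind(spec$grid, cv_accuracy = cv_acc),
                 train_accuracy = mean((p_tr > 0.5) == (y == "more"))),
            class = "telepain_model")
}

apply_standardization <- function(x, std) {
  for (v in names(std$center)) {
    x[, v] <- (x[, v] - std$center[[v]]) / std$scale[[v]]
  }
  x
}

#' Predict tele-visit class probabilities for patient records
#'
#' @param object a `telepain_model`.
#' @param newdata a cohort-like data frame with the feature columns (an
#'   outcome column is not required).
#' @param type `"prob"` for the probability of outcome "more", `"class"`
#'   for the 0.5-thresholded class label.
#' @param ... unused.
#' @return numeric probabilities or a factor of classes.
#' @export
predict.telepain_model <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- apply_standardization(features_design(newdata), object$std)
  p <- predict_inner(object$kind, object$fit, x, object$params)
  p <- pmin(pmax(p, 0), 1)
  if (type == "prob") p else {
    factor(ifelse(p > 0.5, "more", "one"), levels = outcome_levels())
  }
}

#' @exportS3Method
print.telepain_model <- function(x, ...) {
  cat(sprintf("%s classifier (%s): train accuracy %.3f\n", x$label, x$kind,
              x$train_accuracy))
  cat("  params:", paste(sprintf("%s=%g", names(x$params), x$params),
                         collapse = ", "), "\n")
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * precision * recall / (precision + recall)`, with the
#' convention that the score is 0 when precision and recall are both 0.
#'
#' @param precision,recall values in \[0, 1\].
#' @return the F1 score.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Exact (Clopper-Pearson) 95% confidence interval for an accuracy
#'
#' @param correct number of correct classifications.
#' @param n number of classified cases (> 0).
#' @return numeric vector `c(L, U)`.
#' @export
accuracy_ci <- function(correct, n) {
  if (n <= 0) stop("accuracy_ci needs n > 0")
  stopifnot(correct >= 0, correct <= n)
  ci <- binom.test(correct, n)$conf.int
  c(L = ci[1], U = ci[2])
}

#' Exact one-sided test of accuracy against the no-information rate
#'
#' One-sided exact binomial test of the hypothesis that the true accuracy
#' exceeds the no-information rate (the accuracy of always predicting the
#' majority class).
#'
#' @param correct correct classifications; `n` cases.
#' @param n number of cases.
#' @param nir no-information rate, strictly in (0, 1).
#' @return the p-value.
#' @export
acc_vs_nir <- function(correct, n, nir) {
  if (nir <= 0 || nir >= 1) stop("nir must be strictly in (0, 1)")
  unname(binom.test(correct, n, p = nir, alternative = "greater")$p.value)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a randomly chosen positive
#' score ranks above a randomly chosen negative one, with ties counted 1/2.
#' Also returns the ROC curve points (one per distinct score threshold).
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels positive-class indicator: logical, 0/1, or a factor whose
#'   `"more"` level is positive.
#' @return list with `auc` and `curve` (data frame of `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.factor(labels)) labels == "more" else as.logical(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("roc_auc needs both classes present")
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  keep <- !duplicated(scores[ord][seq_along(ord)], fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[keep] / n0), tpr = c(0, tp[keep] / n1))
  list(auc = auc, curve = curve)
}

#' Evaluate a tuned classifier on a held-out test cohort
#'
#' Produces the full metric panel with "more" as the positive class:
#' AUC on the test set (and, when `full` is supplied, over the entire
#' dataset, the variant used for ROC-curve displays), train and test
#' accuracy, the exact Clopper-Pearson 95% interval, the exact one-sided
#' p-value against the no-information rate of the test set, sensitivity,
#' specificity and F1.
#'
#' @param model a `telepain_model`.
#' @param test a non-empty `patient_cohort` disjoint from the training set.
#' @param full optionally the entire (train + test) cohort for the
#'   whole-data AUC.
#' @return a `metrics_report` (named list).
#' @export
evaluate_model <- function(model, test, full = NULL) {
  if (nrow(test) == 0) stop("empty test set")
  y <- factor(as.character(test$outcome), levels = outcome_levels())
  p <- predict(model, test, type = "prob")
  pred <- p > 0.5
  truth <- y == "more"
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  correct <- tp + tn
  n <- length(y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  nir <- max(mean(truth), 1 - mean(truth))
  ci <- accuracy_ci(correct, n)
  auc_full <- NA_real_
  if (!is.null(full)) {
    auc_full <- roc_auc(predict(model, full, type = "prob"),
                        full$outcome)$auc
  }
  structure(list(
    classifier = model$label,
    auc_full = auc_full,
    auc_test = roc_auc(p, y)$auc,
    acc_train = model$train_accuracy,
    acc_test = correct / n,
    L = unname(ci["L"]), U = unname(ci["U"]),
    p_vs_nir = acc_vs_nir(correct, n, nir),
    sensitivity = sens, specificity = spec,
    f1 = f1_score(prec, sens),
    n_test = n, nir = nir
  ), class = "metrics_report")
}

#' @exportS3Method
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "%s: AUC(all) %.2f | AUC(test) %.2f | ACC tr %.2f / tst %.2f [%.2f, %.2f] | p(ACC>NIR) %.2g | sens %.2f | spec %.2f | F1 %.2f\n",
    x$classifier, x$auc_full, x$auc_test, x$acc_train, x$acc_test, x$L,
    x$U, x$p_vs_nir, x$sensitivity, x$specificity, x$f1))
  invisible(x)
}

#' Run the four-classifier bench on a cohort
#'
#' Splits the cohort 80/20 (the remainder goes to the test set), tunes all
#' four classifiers on the training portion by repeated stratified
#' cross-validation, and evaluates each on the test set, returning the
#' combined metric table.
#'
#' @param cohort a `patient_cohort` (typically the pooled real + generated
#'   data).
#' @param seed integer seed driving the split, fold assignment and fits.
#' @param k,repeats cross-validation protocol (default 5 folds x 3
#'   repeats).
#' @param kinds classifier kinds to include.
#' @return a `bench_result`: metric table (`$table`), fitted models
#'   (`$models`) and the split.
#' @export
bench <- function(cohort, seed = 1L, k = 5, repeats = 3,
                  kinds = c("gbm", "rf", "elastic", "ann")) {
  idx <- split_indices(nrow(cohort), 0.8, seed)
  train <- cohort[idx$train, , drop = FALSE]
  test <- cohort[idx$test, , drop = FALSE]
  models <- list()
  reports <- list()
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    m <- tune_classifier(kind, train, k = k, repeats = repeats,
                         seed = seed + i)
    models[[kind]] <- m
    reports[[kind]] <- evaluate_model(m, test, full = cohort)
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(Classifier = r$classifier, AUC = r$auc_full,
               AUC_TST = r$auc_test, ACC_TR = r$acc_train,
               ACC_TST = r$acc_test, L = r$L, U = r$U, P = r$p_vs_nir,
               SENS = r$sensitivity, SPEC = r$specificity, F1 = r$f1)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, models = models, reports = reports,
                 split = idx, seed = seed),
            class = "bench_result")
}

#' @exportS3Method
print.bench_result <- function(x, digits = 2, ...) {
  cat(sprintf("Classifier bench (n train = %d, n test = %d)\n",
              length(x$split$train), length(x$split$test)))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write the bench metric table as CSV
#'
#' @param result a `bench_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bench_table <- function(result, path) {
  write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
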