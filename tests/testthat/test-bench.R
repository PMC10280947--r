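test_that("the feature set excludes metastatic status and has width 18", {
  co <- small_cohort(60, seed = 1)
  f <- features(co)
  expect_false(any(grepl("metastatic", colnames(f$x))))
  expect_equal(ncol(f$x), 18L)
  expect_equal(mean(f$y == "more"), mean(co$n_televisits > 1))
  expect_equal(nrow(f$x), nrow(co))
})

test_that("f1_score follows the printed harmonic-mean formula", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.3, 0), 0)
  expect_equal(f1_score(0, 0), 0)
  # all-positive classifier at test prevalence 0.575: F1 prints as 0.7
  expect_equal(round(f1_score(0.575, 1), 1), 0.7)
  set.seed(3)
  for (i in 1:100) {
    p <- runif(1)
    r <- runif(1)
    expect_equal(f1_score(p, r), 2 * p * r / (p + r), tolerance = 1e-12)
  }
})

test_that("accuracy_ci is the exact Clopper-Pearson interval", {
  expect_equal(unname(accuracy_ci(10, 10)["U"]), 1)
  expect_equal(unname(accuracy_ci(0, 10)["L"]), 0)
  ci <- accuracy_ci(70, 87)
  expect_equal(round(unname(ci["L"]), 1), 0.7)
  expect_equal(round(unname(ci["U"]), 2), 0.88)
  # independent beta-quantile oracle on random inputs
  set.seed(4)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    x <- sample(0:n, 1)
    ci <- accuracy_ci(x, n)
    L <- if (x == 0) 0 else qbeta(0.025, x, n - x + 1)
    U <- if (x == n) 1 else qbeta(0.975, x + 1, n - x)
    expect_equal(unname(ci), c(L, U), tolerance = 1e-9)
  }
  expect_error(accuracy_ci(0, 0), "n > 0")
})

test_that("acc_vs_nir is the exact one-sided binomial tail", {
  expect_gt(acc_vs_nir(50, 100, 0.5), 0.4)
  expect_lt(acc_vs_nir(87, 87, 0.5), 1e-20)
  expect_lt(acc_vs_nir(70, 87, 0.505), 0.01)
  set.seed(5)
  for (i in 1:100) {
    n <- sample(5:150, 1)
    x <- sample(0:n, 1)
    nir <- runif(1, 0.05, 0.95)
    expect_equal(acc_vs_nir(x, n, nir),
                 sum(dbinom(x:n, n, nir)), tolerance = 1e-9)
  }
  expect_error(acc_vs_nir(5, 10, 1), "strictly")
})

test_that("roc_auc equals pairwise ranking probability with ties at 1/2", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 1, 0))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))$auc, 1)
  # brute-force pair-counting oracle on random small inputs
  set.seed(6)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    pos <- which(labels == 1)
    neg <- which(labels == 0)
    pairs <- expand.grid(p = pos, q = neg)
    oracle <- mean(ifelse(scores[pairs$p] > scores[pairs$q], 1,
                          ifelse(scores[pairs$p] == scores[pairs$q],
                                 0.5, 0)))
    expect_equal(roc_auc(scores, labels)$auc, oracle, tolerance = 1e-12)
  }
  # null oracle: uninformative scores give AUC ~ 0.5
  set.seed(7)
  aucs <- replicate(500, roc_auc(runif(200), rbinom(200, 1, 0.5))$auc)
  expect_gt(mean(aucs), 0.48)
  expect_lt(mean(aucs), 0.52)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- runif(80)
  labels <- rbinom(80, 1, 0.5)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           levels = c(0, 1),
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("tuning selects by CV accuracy, deterministically", {
  co <- small_cohort(120, seed = 11)
  m1 <- tune_classifier("elastic", co, seed = 3)
  m2 <- tune_classifier("elastic", co, seed = 3)
  expect_equal(m1$params, m2$params)
  expect_equal(predict(m1, co), predict(m2, co))
  expect_equal(nrow(m1$cv), 1L)          # one-point grid -> that point
  expect_equal(m1$params$alpha, 0)
  expect_equal(m1$params$lambda, 0.25)
  expect_error(classifier_spec("rf", grid = data.frame()), "empty")
})

test_that("classifiers detect a separable synthetic signal", {
  # linearly separable outcome: driven entirely by MED class
  co <- small_cohort(200, seed = 12)
  co$n_televisits <- ifelse(co$med_gt60 == 1, 3L, 1L)
  co$outcome <- factor(ifelse(co$med_gt60 == 1, "more", "one"),
                       levels = c("one", "more"))
  m <- tune_classifier("elastic", co, seed = 13)
  expect_gte(m$cv$cv_accuracy, 0.95)
  rf <- tune_classifier("rf", co, seed = 14)
  rep <- evaluate_model(rf, co)
  expect_gte(rep$acc_test, 0.95)
})

test_that("evaluate_model matches a hand-computed confusion matrix", {
  co <- small_cohort(150, seed = 15)
  train <- co[1:110, ]
  test <- co[111:150, ]
  m <- tune_classifier("rf", train, seed = 16)
  rep <- evaluate_model(m, test, full = co)
  p <- predict(m, test, type = "prob")
  pred <- p > 0.5
  truth <- test$outcome == "more"
  expect_equal(rep$acc_test, mean(pred == truth))
  expect_equal(rep$sensitivity, sum(pred & truth) / sum(truth))
  expect_equal(rep$specificity, sum(!pred & !truth) / sum(!truth))
  prec <- if (sum(pred) > 0) sum(pred & truth) / sum(pred) else 0
  expect_equal(rep$f1, f1_score(prec, rep$sensitivity))
  expect_true(rep$L <= rep$acc_test && rep$acc_test <= rep$U)
  expect_true(all(unlist(rep[c("auc_full", "auc_test", "acc_train",
                               "acc_test", "L", "U", "p_vs_nir",
                               "sensitivity", "specificity", "f1")])
                  >= 0))
  expect_error(evaluate_model(m, test[0, ]), "empty")
})

test_that("every bench classifier finds signal in a pooled cohort", {
  spec <- default_spec()
  spec$n <- 1000L
  pooled <- pool_cohorts(sample_cohort(spec, seed = 17),
                         sample_cohort(spec, seed = 18))
  res <- bench(pooled, seed = 19, k = 5, repeats = 1)
  expect_equal(nrow(res$table), 4L)
  expect_setequal(res$table$Classifier, c("GBM", "RF", "LASSO", "ANN"))
  expect_true(all(res$table$AUC_TST > 0.5))
  expect_true(all(res$table$L <= res$table$ACC_TST &
                  res$table$ACC_TST <= res$table$U))
  num <- unlist(res$table[, -1])
  expect_true(all(num >= 0 & num <= 1))
})
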