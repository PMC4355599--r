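# Two-Gaussian synthetic feature cohorts for classifier tests.
make_gauss_cohort <- function(seed, n = 200, p = 30, informative = 1:3,
                              delta = 2) {
  set.seed(seed)
  y <- rep(c("low", "high"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[y == "high", informative] <- x[y == "high", informative] + delta
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}

test_that("the class-weight rule is the reciprocal of the count ratio", {
  expect_equal(class_weight_ratio(119, 29), 119 / 29)
  expect_equal(class_weight_ratio(50, 50), 1)
  expect_equal(class_weight_ratio(2, 1), 2)
  expect_equal(class_weight_ratio(3, 7) * class_weight_ratio(7, 3), 1)
  expect_error(class_weight_ratio(0, 5))
})

test_that("confusion-derived indices match the published worked example", {
  cm <- confusion_matrix(
    truth = rep(c("high", "high", "low", "low"), c(23, 6, 103, 16)),
    predicted = rep(c("high", "low", "low", "high"), c(23, 6, 103, 16)))
  expect_equal(cm$TP, 23); expect_equal(cm$FN, 6)
  expect_equal(cm$TN, 103); expect_equal(cm$FP, 16)
  m <- metrics_from_confusion(cm)
  expect_equal(unname(m["accuracy"]), 126 / 148)
  expect_equal(round(100 * unname(m["accuracy"]), 2), 85.14)
  expect_equal(round(100 * unname(m["sensitivity"]), 2), 79.31)
  expect_equal(round(100 * unname(m["specificity"]), 2), 86.55)
  expect_equal(round(100 * unname(m["PPV"]), 2), 58.97)
  expect_equal(round(100 * unname(m["NPV"]), 2), 94.50)
})

test_that("degenerate confusion denominators give NA; perfect gives all ones", {
  m0 <- metrics_from_confusion(list(TP = 0, FN = 0, TN = 5, FP = 2))
  expect_true(is.na(m0[["sensitivity"]]))
  expect_false(anyNA(m0[c("accuracy", "specificity", "NPV")]))
  mp <- metrics_from_confusion(list(TP = 10, FN = 0, TN = 20, FP = 0))
  expect_equal(unname(mp), rep(1, 5))
})

test_that("A_Z is the Mann-Whitney statistic with its symmetries", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), rep(c("low", "high"), c(3, 2))), 1)
  set.seed(19)
  sc <- rnorm(1000)
  lab <- sample(rep(c("low", "high"), 500))
  expect_lt(abs(roc_auc(sc, lab) - 0.5), 0.03)
  expect_equal(roc_auc(-sc, lab), 1 - roc_auc(sc, lab))
  # ties counted one half
  expect_equal(roc_auc(c(1, 1), c("low", "high")), 0.5)
  expect_error(roc_auc(1:3, rep("low", 3)), "both classes")
  # agrees with an independent ROC implementation
  expect_equal(roc_auc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("low", "high"),
                                              direction = "<", quiet = TRUE))))
})

test_that("the GA fitness arithmetic and its trade-off are exact", {
  expect_equal(ga_fitness(1, 1, 1), 1)
  expect_equal(ga_fitness(0.8, 0.9, 10), 0.596)
  expect_equal(ga_fitness(0, 0.7, 44), 0.2 / 44)
  # parsimony: a slightly weaker model with 5 features beats 44 features
  f5 <- ga_fitness(0.9, 0.9, 5)
  f44 <- ga_fitness(0.92, 0.92, 44)
  expect_equal(f5, 0.688)
  expect_equal(round(f44, 3), 0.682)
  expect_gt(f5, f44)
  # monotone in k and in the product
  expect_gt(ga_fitness(0.9, 0.9, 5), ga_fitness(0.9, 0.9, 6))
  expect_gt(ga_fitness(0.95, 0.9, 5), ga_fitness(0.9, 0.9, 5))
  expect_error(ga_fitness(0.9, 0.9, 0))
})

test_that("the GA is reproducible, monotone under elitism, and finds signal", {
  co <- make_gauss_cohort(1)
  ga <- ga_config(population = 24L, generations = 20L, inner_folds = 3L)
  fit <- ga_svm(co$x, co$y, ga = ga, seed = 42)
  expect_s3_class(fit, "ga_svm")
  expect_true(all(diff(fit$trace) >= 0))    # elitism: best never degrades
  fit2 <- ga_svm(co$x, co$y, ga = ga, seed = 42)
  expect_identical(fit$features, fit2$features)
  expect_equal(fit$C, fit2$C)
  expect_equal(fit$gamma, fit2$gamma)
  expect_equal(fit$trace, fit2$trace)
  # recovery of planted informative features across independent runs
  hits <- vapply(1:5, function(s) {
    f <- ga_svm(co$x, co$y, ga = ga, seed = s)
    sum(c("f1", "f2", "f3") %in% f$features)
  }, numeric(1))
  expect_gte(mean(hits >= 2), 0.8)
})

test_that("ga_svm validates its inputs and predicts on new data", {
  co <- make_gauss_cohort(2, n = 60, p = 6)
  ga <- ga_config(population = 10L, generations = 5L, inner_folds = 3L)
  fit <- ga_svm(co$x, co$y, ga = ga, seed = 7)
  pr <- predict(fit, co$x)
  expect_s3_class(pr, "factor")
  expect_gt(mean(pr == co$y), 0.7)
  sc <- predict(fit, co$x, type = "score")
  expect_gt(roc_auc(sc, co$y), 0.8)
  expect_equal(coef(fit)$features, fit$features)
  bad <- co$x; bad[1, 1] <- NA
  expect_error(ga_svm(bad, co$y, ga = ga), "missing values")
  expect_error(predict(fit, co$x[, -1, drop = FALSE])
               , "lacks features")
})

test_that("tenfold CV separates separable cohorts and not permuted ones", {
  co <- make_gauss_cohort(3, n = 200, p = 10, informative = 1:3, delta = 4)
  cv <- tenfold_cv(co$x, co$y, C = 1, gamma = 0.1, seed = 9)
  expect_gte(cv$metrics[["accuracy"]], 0.95)
  expect_gte(cv$metrics[["A_Z"]], 0.99)
  # internal consistency: reported metrics equal those recomputed from the
  # stored pooled confusion matrix
  expect_equal(cv$metrics[names(metrics_from_confusion(cv$confusion))],
               metrics_from_confusion(cv$confusion))
  expect_equal(sum(cv$per_fold$TP) , cv$confusion$TP)
  # shuffled labels: chance-level A_Z
  set.seed(10)
  ysh <- sample(co$y)
  cvn <- tenfold_cv(co$x, ysh, C = 1, gamma = 0.1, seed = 9)
  expect_lt(abs(cvn$metrics[["A_Z"]] - 0.5), 0.05)
})

test_that("stratified folds keep both classes in every fold", {
  co <- make_gauss_cohort(4, n = 60, p = 4)
  cv <- tenfold_cv(co$x, co$y, C = 1, gamma = 0.25, k = 10L, seed = 2)
  tab <- table(cv$folds, co$y)
  expect_true(all(tab > 0))
  idx <- c(1:6, 31:36)   # 6 cases per class: folds must lose a class
  expect_error(tenfold_cv(co$x[idx, ], co$y[idx], k = 10L, seed = 2),
               "fold")
})
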