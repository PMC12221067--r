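test_that("confusion counts are standard, with class 1 positive", {
  y <- rep(c(1, 0), each = 10)
  expect_equal(unclass(confusion(y, y))[c("TP", "TN", "FP", "FN")],
               list(TP = 10L, TN = 10L, FP = 0L, FN = 0L))
  allpos <- confusion(y, rep(1, 20))
  expect_equal(allpos$TP, 10)
  expect_equal(allpos$FP, 10)
  expect_equal(allpos$TN + allpos$FN, 0)
  expect_error(confusion(y, y[-1]), "length")
  expect_error(confusion(y, rep(2, 20)), "binary")
  # swapping predictions exchanges the error types, checked by recount
  set.seed(31)
  yt <- rbinom(40, 1, 0.5); yp <- rbinom(40, 1, 0.5)
  a <- confusion(yt, yp); b <- confusion(yt, 1 - yp)
  expect_equal(b$FP, sum(yt == 0 & (1 - yp) == 1))
  expect_equal(a$TN, b$FP)
  expect_equal(a$TP, b$FN)
})

test_that("the nine metrics match hand arithmetic on (50,10,5,35)", {
  m <- classification_metrics(list(TP = 50, FP = 10, FN = 5, TN = 35))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 50 / 60)
  expect_equal(m$sensitivity, 50 / 55)
  expect_equal(m$specificity, 35 / 45)
  expect_equal(m$f1, 2 * (50 / 60) * (50 / 55) / (50 / 60 + 50 / 55))
  expect_equal(m$npv, 35 / 40)
  expect_equal(m$mcc,
               (50 * 35 - 10 * 5) / sqrt(60) / sqrt(55) / sqrt(45) / sqrt(40))
  expect_equal(m$fpr, 1 - m$specificity)
  expect_equal(m$fnr, 1 - m$sensitivity)
})

test_that("perfect counts give perfect metrics; zero denominators go NA", {
  p <- classification_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(unlist(p[c("accuracy", "precision", "sensitivity",
                                 "specificity", "f1", "mcc", "npv")])),
               rep(1, 7))
  expect_equal(p$fpr + p$fnr, 0)
  warns <- capture_warnings(
    z <- classification_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)))
  expect_true(any(grepl("precision", warns)))
  expect_true(is.na(z$precision))
  expect_true(is.na(z$f1))
  expect_error(classification_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "zero total")
})

test_that("metric ranges and complement identities hold on random counts", {
  set.seed(17)
  for (i in 1:20) {
    cts <- as.list(stats::setNames(rpois(4, 20) + 1,
                                   c("TP", "TN", "FP", "FN")))
    m <- classification_metrics(cts)
    vals <- unlist(m[c("accuracy", "precision", "sensitivity",
                       "specificity", "f1", "npv", "fpr", "fnr")])
    expect_true(all(vals >= 0 & vals <= 1))
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    expect_equal(m$fpr, 1 - m$specificity)
    expect_equal(m$fnr, 1 - m$sensitivity)
  }
})

test_that("ROC/AUC matches the concordant-pair statistic", {
  r <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(rep(1, 4), runif(4)), "both classes")
  # brute-force pair counting on random toys, plus monotone invariance
  set.seed(23)
  for (i in 1:10) {
    n <- sample(6:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- rnorm(n)
    pairs <- expand.grid(p = which(y == 1), q = which(y == 0))
    conc <- mean(ifelse(s[pairs$p] > s[pairs$q], 1,
                        ifelse(s[pairs$p] == s[pairs$q], 0.5, 0)))
    expect_equal(roc_auc(y, s)$auc, conc, tolerance = 1e-12)
    expect_equal(roc_auc(y, exp(3 * s))$auc, roc_auc(y, s)$auc)
  }
})

test_that("ROC/AUC agrees with an established reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60) + y
  ours <- roc_auc(y, s)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("k-fold evaluation stratifies, partitions, and aggregates", {
  set.seed(41)
  tbl <- make_feature_dataset(n_per_class = 20, n_informative = 2,
                              n_noise = 3, effect_size = 4, seed = 5)
  factory <- function(xs, y) {
    X <- do.call(rbind, xs)
    list(X = X, y = y)
  }
  predict_fn <- function(model, xs) {
    Xte <- do.call(rbind, xs)
    fasftle:::nearest_centroid_predict(model$X, model$y, Xte)
  }
  cv <- kfold_evaluate(tbl, factory, predict_fn, k = 5, seed = 2)
  folds <- cv$fold_assignment
  expect_setequal(unique(folds), 1:5)
  y <- ft_labels(tbl)
  for (f in 1:5) {
    # stratification: per-fold class counts within 1 of n/k
    expect_lte(abs(sum(y[folds == f] == 1) - 4), 1)
  }
  expect_gte(cv$summary[[
    "accuracy"]][cv$summary$statistic == "mean"], 0.95)
  expect_equal(nrow(cv$folds), 5)
  expect_error(kfold_evaluate(tbl, factory, predict_fn, k = 25, seed = 1),
               "fewer than k")
})

test_that("eval reports serialise with the standard header names", {
  dir <- withr::local_tempdir()
  rep <- eval_report(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  p <- file.path(dir, "report.json")
  write_eval_report(rep, p)
  back <- jsonlite::read_json(p)
  expect_named(back$metrics,
               c("Accuracy", "Precision", "Sensitivity", "Specificity",
                 "F1-Score", "MCC", "NPV", "FPR", "FNR"))
  expect_equal(back$auc, 0.75)
  expect_equal(back$counts$TP, 1)
})
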