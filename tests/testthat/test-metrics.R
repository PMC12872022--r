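test_that("precision/recall/F1 handle worked and degenerate cases", {
  cc <- confusion_counts(tp = 5, fp = 0, fn = 2, tn = 10)
  prf <- precision_recall_f1(cc)
  expect_equal(unname(prf["precision"]), 1.0)
  expect_equal(unname(prf["recall"]), 5 / 7, tolerance = 1e-12)
  expect_equal(precision_recall_f1(confusion_counts(0, 0, 0, 10)),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(f1_from_pr(0.84, 1.00), 2 * 0.84 / 1.84, tolerance = 1e-12)
  expect_equal(round(f1_from_pr(1.00, 0.76), 2), 0.86)
  # harmonic-mean bound
  set.seed(12)
  for (i in 1:20) {
    P <- runif(1); R <- runif(1)
    f <- f1_from_pr(P, R)
    expect_gte(f, min(P, R) - 1e-12)
    expect_lte(f, max(P, R) + 1e-12)
  }
})

test_that("MCC matches its closed form and symmetry", {
  expect_equal(mcc(confusion_counts(10, 0, 0, 5)), 1.0)
  expect_equal(mcc(confusion_counts(0, 5, 10, 0)), -1.0)
  expect_equal(mcc(confusion_counts(5, 0, 2, 10)), 50 / sqrt(4200),
               tolerance = 1e-12)
  expect_equal(mcc(confusion_counts(0, 0, 3, 7)), 0)
  # symmetric under TP<->TN, FP<->FN swap
  expect_equal(mcc(confusion_counts(5, 1, 2, 10)),
               mcc(confusion_counts(10, 2, 1, 5)), tolerance = 1e-12)
})

test_that("bootstrap CI is exact on perfect predictions and reorder
           invariant", {
  y <- c(rep(1, 20), rep(0, 30))
  ci <- bootstrap_ci(y, y, "f1", n = 200, seed = 1)
  expect_equal(ci$mean, 1.0)
  expect_equal(c(ci$lo, ci$hi), c(1.0, 1.0))
  set.seed(44)
  yp <- ifelse(runif(50) < 0.8, y, 1 - y)
  a <- bootstrap_ci(y, yp, "f1", n = 300, seed = 2)
  perm <- sample(50)
  b <- bootstrap_ci(y[perm], yp[perm], "f1", n = 300, seed = 2)
  expect_identical(a, b)
  expect_lte(a$lo, a$mean)
  expect_gte(a$hi, a$mean)
  expect_error(bootstrap_ci(rep(0, 10), rep(0, 10), "recall", n = 50,
                            seed = 1), "undefined")
})

test_that("bootstrap interval covers a known accuracy at nominal rate", {
  set.seed(29)
  truth <- 0.8
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    y <- rbinom(500, 1, 0.5)
    yp <- ifelse(runif(500) < truth, y, 1 - y)
    ci <- bootstrap_ci(y, yp, "accuracy", n = 1000, seed = r)
    if (ci$lo <= truth && truth <= ci$hi) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
  expect_lte(hits / reps, 0.99)
})

test_that("paired t-test matches hand computation and rejects zero
           variance", {
  a <- c(2, 4, 6, 5, 3); b <- a - c(1, 2, 3, 2, 1)
  res <- paired_ttest(a, b)
  expect_equal(res$t, 1.8 / (sd(c(1, 2, 3, 2, 1)) / sqrt(5)),
               tolerance = 1e-6)
  expect_error(paired_ttest(a, a), "zero variance")
  big <- seq(1, 5) + 10; small <- seq(1, 5) + c(0.01, 0.02, 0.01, 0.03, 0.02)
  expect_gt(paired_ttest(big, small)$t, 0)
})

test_that("Pearson correlation matches the closed form", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  y <- c(2, 1, 4, 3, 6)
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), want, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
})

test_that("KO-based benchmarking maps annotations to confusion cells", {
  truth <- list(PET = c("a", "b"), PHB = c("c"), negative = c("d", "e"))
  preds <- c(a = "K21104", b = "K00001", c = "K05973", d = "K03932",
             e = NA)
  cc <- benchmark_confusion(preds, truth, scheme = "ko")
  expect_equal(cc$PET$tp, 1); expect_equal(cc$PET$fn, 1)
  expect_equal(cc$PET$fp, 1); expect_equal(cc$PET$tn, 1)
  expect_equal(cc$PHB$tp, 1); expect_equal(cc$PHB$fn, 0)
  bad_truth <- list(PET = c("a"), PHB = c("a"), negative = "d")
  expect_error(benchmark_confusion(preds, bad_truth, scheme = "ko"),
               "two truth sets")
})

test_that("score-based benchmarking uses a strict 0.5 threshold", {
  truth <- list(PET = c("a", "b"), negative = c("d"))
  sc <- matrix(c(0.4, 0.51, 0.5), 3, 1,
               dimnames = list(c("a", "b", "d"), "PET"))
  cc <- benchmark_confusion(sc, truth, scheme = "score")
  expect_equal(cc$PET$fn, 1)   # 0.4 below threshold
  expect_equal(cc$PET$tp, 1)   # 0.51 above
  expect_equal(cc$PET$tn, 1)   # 0.5 is not "exceeding 0.5"
})

test_that("hits per million proteins normalizes correctly", {
  expect_equal(hits_per_million(1, 1e6), 1.0)
  expect_equal(hits_per_million(0, 123), 0.0)
  expect_equal(hits_per_million(2, 4e6), 0.5)
  expect_error(hits_per_million(1, 0), ">= 1")
})

test_that("evaluation reports carry metrics and ordered CI bounds", {
  set.seed(31)
  y <- rbinom(80, 1, 0.4)
  yp <- ifelse(runif(80) < 0.85, y, 1 - y)
  row <- evaluation_report("PET", "default", y, yp, n_bootstrap = 200,
                           seed = 3)
  expect_true(all(c("precision", "recall", "f1", "mcc") %in% names(row)))
  for (m in c("precision", "recall", "f1")) {
    expect_lte(row[[paste0(m, "_lo")]], row[[paste0(m, "_hi")]])
  }
})
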