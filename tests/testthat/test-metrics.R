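test_that("confusion counts are exact and validated", {
  cm <- confusion(c(1, 1, 0), c(1, 0, 0))
  expect_identical(cm[c("tp", "fn", "tn", "fp")],
                   list(tp = 1L, fn = 1L, tn = 1L, fp = 0L))
  same <- confusion(c("MM", "NM"), c("MM", "NM"))
  expect_identical(same$fp + same$fn, 0L)
  expect_error(confusion(c(1, 0), c(1)), "equal length")
  expect_error(confusion(integer(0), integer(0)), "non-empty")
  expect_error(confusion(c("MM", "XX"), c("MM", "NM")), "unrecognized")
  # patch-level label vocabulary is accepted too
  cm2 <- confusion(c("MALIGNANT", "NON_MALIGNANT"), c("MALIGNANT", "MALIGNANT"))
  expect_identical(cm2$fp, 1L)
})

test_that("slide-level worked example reproduces the reference metrics", {
  # 32 test slides, 8 malignant with 2 missed, all 24 non-malignant correct
  cm <- confusion_counts(tp = 6, fn = 2, tn = 24, fp = 0)
  m <- metrics(cm)
  expect_equal(round(m$acc, 1), 93.8)
  expect_equal(round(m$sen, 1), 75.0)
  expect_equal(round(m$spe, 1), 100.0)
  expect_equal(round(m$kappa, 3), 0.818)
  expect_equal(m$b_acc, (m$sen + m$spe) / 2)
})

test_that("kappa hits its closed-form anchors", {
  perfect <- metrics(confusion_counts(tp = 5, fn = 0, tn = 7, fp = 0))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$kappa, 1)
  # a constant predictor has observed agreement equal to chance agreement
  constant <- metrics(confusion_counts(tp = 0, fn = 4, tn = 9, fp = 0))
  expect_equal(constant$kappa, 0)
  # swapping the positive/negative designation: acc and kappa invariant,
  # sensitivity and specificity exchange
  a <- metrics(confusion_counts(tp = 6, fn = 2, tn = 24, fp = 3))
  b <- metrics(confusion_counts(tp = 24, fn = 3, tn = 6, fp = 2))
  expect_equal(a$kappa, b$kappa)
  expect_equal(a$acc, b$acc)
  expect_equal(a$sen, b$spe)
  expect_equal(a$spe, b$sen)
  # zero denominators flagged, not silently zeroed
  und <- metrics(confusion_counts(tp = 0, fn = 0, tn = 5, fp = 2))
  expect_true(is.nan(und$sen))
  expect_true("sen" %in% und$undefined)
})

test_that("rank AUC matches enumeration, ties and reversal laws", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  # 4 positive-negative pairs: 3 wins, 1 loss
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc, 0.75)
  set.seed(17)
  y <- rep(c(1, 0), c(12, 20))
  s <- c(rnorm(12, 1), rnorm(20))
  expect_equal(roc_auc(y, s)$auc, 1 - roc_auc(y, -s)$auc)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  expect_error(roc_auc(c(1, 0), c(NaN, 0.3)), "finite")
})

test_that("rank AUC equals the trapezoidal area under its own ROC", {
  for (seed in 1:5) {
    set.seed(seed)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(rnorm(40), 1)  # coarse scores force ties
    r <- roc_auc(y, s)
    trap <- sum(diff(r$roc$fpr) * (utils::head(r$roc$tpr, -1) +
                                     utils::tail(r$roc$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent implementation", {
  set.seed(23)
  y <- rbinom(60, 1, 0.3)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  s <- rnorm(60) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
})
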