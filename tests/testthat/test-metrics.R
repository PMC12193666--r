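test_that("threshold metrics match independent arithmetic on the printed table", {
  cm <- confusion_counts(tp = 2030, tn = 2546, fp = 74, fn = 449)
  m <- compute_metrics(cm)
  o <- arithmetic_metrics(2030, 2546, 74, 449)
  expect_equal(m$accuracy, o$acc, tolerance = 1e-12)     # 0.897431
  expect_equal(m$sensitivity, o$se, tolerance = 1e-12)   # 0.818879
  expect_equal(m$specificity, o$sp, tolerance = 1e-12)   # 0.971756
  expect_equal(m$precision, o$precision, tolerance = 1e-12)
  expect_equal(m$f1, o$f1, tolerance = 1e-12)
  expect_equal(m$mcc, o$mcc, tolerance = 1e-12)
  # frozen values from the arithmetic oracle
  expect_equal(m$accuracy, 0.897431, tolerance = 1e-6)
  expect_equal(m$sensitivity, 0.818879, tolerance = 1e-6)
  expect_equal(m$specificity, 0.971756, tolerance = 1e-6)
})

test_that("perfect and degenerate confusion matrices behave as defined", {
  perfect <- compute_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(unlist(perfect[1, ]), setNames(rep(1, 6), names(perfect)))

  deg <- compute_metrics(confusion_counts(0, 10, 0, 5))
  expect_equal(deg$precision, 0)
  expect_equal(deg$mcc, 0)
  expect_setequal(attr(deg, "zero_denominator"), c("precision", "mcc"))
  expect_equal(deg$f1, 0)   # defined: TP = 0 over a positive denominator
  expect_error(compute_metrics(confusion_counts(-1, 1, 1, 1)), "nonnegative")
})

test_that("AUROC equals the pairwise probability with ties at one half", {
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1)), 0.75)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auroc(c(0, 1), c(0.9, 0.1)), 0)
})

test_that("roc/pr agree with brute-force oracles on all small inputs", {
  set.seed(55)
  for (n in 2:8) {
    for (rep in 1:40) {
      truth <- sample(0:1, n, replace = TRUE)
      if (length(unique(truth)) < 2) next
      # discrete scores force plenty of ties
      scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      expect_equal(auroc(truth, scores), pairwise_auroc(truth, scores),
                   tolerance = 1e-12)
      expect_equal(roc_curve(truth, scores)$auc,
                   pairwise_auroc(truth, scores), tolerance = 1e-12)
      expect_equal(pr_curve(truth, scores)$auc,
                   threshold_auprc(truth, scores), tolerance = 1e-12)
    }
  }
})

test_that("AUROC is antisymmetric under score negation", {
  set.seed(56)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(stats::rnorm(n), 1)
    expect_equal(auroc(truth, scores) + auroc(truth, -scores), 1,
                 tolerance = 1e-12)
  }
})

test_that("ranking curves demand both classes and finite scores", {
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), "both classes")
  expect_error(roc_curve(c(0, 1), c(NA, 1)), "finite")
})

test_that("chi-square test matches expected-cell arithmetic and stats::pchisq", {
  # identical rows: perfect independence
  ind <- chi_square_test(confusion_counts(10, 10, 10, 10))
  expect_equal(ind$chi2, 0)
  expect_equal(ind$p_value, 1)
  expect_equal(ind$df, 1L)

  # chi2 = 3.841 at df 1 sits at p ~ 0.050
  expect_equal(stats::pchisq(3.841, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-3)

  res <- chi_square_test(confusion_counts(2030, 2546, 74, 449))
  o <- arithmetic_metrics(2030, 2546, 74, 449)
  expect_equal(res$chi2, o$chi2_direct, tolerance = 1e-9)
  expect_equal(res$chi2, 5099 * o$mcc^2, tolerance = 1e-9)  # ~3285.27
  # no continuity correction: matches the uncorrected classical test
  ref <- stats::chisq.test(matrix(c(2030, 449, 74, 2546), 2), correct = FALSE)
  expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-9)

  expect_error(chi_square_test(confusion_counts(5, 0, 5, 0)), "marginal")
})

test_that("chi2 equals N * MCC^2 on random nondegenerate 2x2 tables", {
  set.seed(57)
  tested <- 0
  while (tested < 200) {
    cells <- sample(0:60, 4, replace = TRUE)
    cm <- confusion_counts(cells[1], cells[2], cells[3], cells[4])
    obs <- matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2)
    if (any(rowSums(obs) == 0) || any(colSums(obs) == 0)) next
    n <- sum(cells)
    mcc <- compute_metrics(cm)$mcc
    expect_equal(chi_square_test(cm)$chi2, n * mcc^2, tolerance = 1e-9)
    tested <- tested + 1
  }
})

test_that("Cohen's kappa matches its definition and the printed table", {
  expect_equal(cohens_kappa(confusion_counts(50, 50, 0, 0))$kappa, 1)
  expect_equal(cohens_kappa(confusion_counts(25, 25, 25, 25))$kappa, 0)
  k <- cohens_kappa(confusion_counts(2030, 2546, 74, 449))
  o <- arithmetic_metrics(2030, 2546, 74, 449)
  expect_equal(k$kappa, o$kappa, tolerance = 1e-12)
  expect_equal(k$kappa, 0.793866, tolerance = 1e-6)   # ~0.794
  expect_equal(k$po, o$acc, tolerance = 1e-12)

  deg <- cohens_kappa(confusion_counts(10, 0, 0, 0))
  expect_true(is.na(deg$kappa))
  expect_true(attr(deg, "kappa_undefined"))
})

test_that("kappa never exceeds accuracy; kappa = 1 iff no errors", {
  set.seed(58)
  for (i in 1:100) {
    cells <- sample(0:40, 4, replace = TRUE)
    if (sum(cells) == 0) next
    cm <- confusion_counts(cells[1], cells[2], cells[3], cells[4])
    k <- cohens_kappa(cm)
    if (is.na(k$kappa)) next
    acc <- compute_metrics(cm)$accuracy
    expect_lte(k$kappa, acc + 1e-12)
    if (cm$fp == 0 && cm$fn == 0 && cm$tp > 0 && cm$tn > 0) {
      expect_equal(k$kappa, 1)
    }
    if (abs(k$kappa - 1) < 1e-12) {
      expect_true(cm$fp == 0 && cm$fn == 0)
    }
  }
})

test_that("own ROC implementation agrees with pROC on a larger sample", {
  skip_if_not_installed("pROC")
  set.seed(59)
  truth <- sample(0:1, 300, replace = TRUE, prob = c(0.6, 0.4))
  truth[1:2] <- 0:1
  scores <- stats::rnorm(300) + truth
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores)))
  expect_equal(auroc(truth, scores), as.numeric(ref), tolerance = 1e-12)
})

test_that("curve objects plot", {
  truth <- c(1, 0, 1, 0, 1, 0)
  scores <- c(0.9, 0.2, 0.7, 0.4, 0.3, 0.6)
  expect_s3_class(autoplot(roc_curve(truth, scores)), "ggplot")
  expect_s3_class(autoplot(pr_curve(truth, scores)), "ggplot")
})
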