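test_that("AUC handles separation, overlap and ties", {
  expect_equal(roc_auc(c(4, 5, 6, 1, 2, 3), c(T, T, T, F, F, F))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 1, 2, 3), c(T, T, T, F, F, F))$auc, 0.5)
  # brute-force pair counting with a half for the tie: 8.5 of 9 pairs
  expect_equal(roc_auc(c(3, 4, 5, 1, 2, 3), c(T, T, T, F, F, F))$auc, 8.5 / 9)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("ROC curve runs from (0,0) to (1,1) with monotone coordinates", {
  set.seed(3)
  r <- roc_auc(c(rnorm(40, 1), rnorm(30)), rep(c(TRUE, FALSE), c(40, 30)))
  expect_equal(unlist(r$curve[1, c("fpr", "tpr")], use.names = FALSE),
               c(0, 0))
  expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")],
                      use.names = FALSE), c(1, 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("own AUC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- c(rnorm(50, 0.5), rnorm(40))
  labels <- rep(c(TRUE, FALSE), c(50, 40))
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("Hanley-McNeil interval behaves at the extremes", {
  wide <- auc_confidence_interval(0.71, 836, 65)
  expect_true(wide[1] < 0.71 && wide[2] > 0.71)
  expect_lt(wide[2] - wide[1], 0.25)
  tight <- auc_confidence_interval(0.5, 1e6, 1e6)
  expect_lt(tight[2] - tight[1], 0.005)
  degen <- auc_confidence_interval(1, 50, 50)
  expect_true(attr(degen, "degenerate"))
  expect_equal(unclass(degen)[1:2], c(1, 1))
})

test_that("likelihood ratios reproduce the published table rows", {
  # rows 39-40 are excluded: their printed LR values do not recompute from
  # the printed sensitivity/specificity at 2 dp (source rounding)
  tab <- printed_roc_table()[-(1:2), ]
  for (i in seq_len(nrow(tab))) {
    lr <- likelihood_ratios(tab$sensitivity[i], tab$specificity[i])
    expect_equal(round(lr$lr_pos, 2), tab$lr_pos[i])
    expect_equal(round(lr$lr_neg, 2), tab$lr_neg[i])
  }
})

test_that("cutoff metric tables are monotone with positive = score > cutoff", {
  set.seed(5)
  scores <- c(rnorm(60, 44, 4), rnorm(50, 40, 5))
  labels <- rep(c(TRUE, FALSE), c(60, 50))
  tab <- cutoff_metrics_table(scores, labels, 36:50)
  expect_true(all(diff(tab$sensitivity) <= 0))
  expect_true(all(diff(tab$specificity) >= 0))
  low <- cutoff_metrics_table(scores, labels, min(scores) - 1)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
  expect_equal(low$lr_pos, 1)
  expect_error(cutoff_metrics_table(scores, labels, numeric(0)), "empty")
})

test_that("Youden selection maximizes J with ties to the smaller cutoff", {
  expect_equal(as.numeric(youden_from_table(printed_roc_table())), 41)
  # perfect separation: J = 1 at the separating cutoff
  ct <- youden_optimal_cutoff(c(5, 6, 7, 1, 2, 3),
                              rep(c(TRUE, FALSE), each = 3), 1:7)
  expect_equal(attr(ct, "J"), 1)
  expect_true(ct >= 3 && ct < 5)
  # identical distributions: J = 0 everywhere, smallest candidate returned
  same <- youden_optimal_cutoff(c(1, 2, 3, 1, 2, 3),
                                rep(c(TRUE, FALSE), each = 3), 1:3)
  expect_equal(as.numeric(same), 1)
  expect_equal(attr(same, "J"), 0)
})

test_that("Spearman correlation handles monotonicity, reversal and ties", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(spearman_rho(x, exp(x))$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  # hand-ranked tied example: ranks x = (1, 2.5, 2.5, 4), y = (1, 3, 2, 4)
  xr <- c(1, 2.5, 2.5, 4); yr <- c(1, 3, 2, 4)
  hand <- sum((xr - mean(xr)) * (yr - mean(yr))) /
    sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4))$rho, hand)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Mann-Whitney U matches its defining identities", {
  expect_equal(mann_whitney_u(4:6, 1:3)$U, 9)
  expect_equal(mann_whitney_u(1:3, 4:6)$U, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
  # U equals the base-R wilcox statistic
  set.seed(2)
  x <- rnorm(20); y <- rnorm(15)
  expect_equal(mann_whitney_u(x, y)$U,
               unname(stats::wilcox.test(x, y, exact = FALSE)$statistic))
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(13)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  a0 <- roc_auc(scores, labels)$auc
  for (f in list(function(x) 3 * x + 7, function(x) exp(x),
                 function(x) x^3)) {
    expect_equal(roc_auc(f(scores), labels)$auc, a0)
  }
})

test_that("the Youden cutoff concentrates on 41 cm under the cohort defaults", {
  cuts <- vapply(1:40, function(s) {
    sc <- generate_screening_cohorts(seed = s)
    as.numeric(youden_optimal_cutoff(sc$neck_circumference, sc$osa_label,
                                     39:46))
  }, 0)
  expect_equal(as.numeric(names(which.max(table(cuts)))), 41)
  expect_gte(mean(cuts >= 40 & cuts <= 43), 0.70)
})
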