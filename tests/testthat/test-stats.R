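test_that("descriptive statistics use the sample convention", {
  d <- descriptives(c(2, 4))
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2))
  expect_equal(d$n, 2L)
  one <- descriptives(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  expect_equal(descriptives(rep(7, 10))$sd, 0)
  expect_error(descriptives(numeric(0)), "no values")
})

test_that("limits of agreement are the mean plus/minus exactly two sample SDs", {
  cst <- limits_of_agreement(rep(1.3, 5))
  expect_equal(c(cst$mean_difference, cst$loa_low, cst$loa_high),
               c(1.3, 1.3, 1.3))
  two <- limits_of_agreement(c(-1, 1))
  expect_equal(two$mean_difference, 0)
  expect_equal(two$sd, sqrt(2))
  expect_equal(two$loa_high, 2 * sqrt(2))
  expect_equal(two$loa_low, -2 * sqrt(2))
  # linearity under scaling
  set.seed(3)
  x <- stats::rnorm(50)
  a <- limits_of_agreement(x)
  b <- limits_of_agreement(3.7 * x)
  expect_equal(b$mean_difference, 3.7 * a$mean_difference)
  expect_equal(b$loa_low, 3.7 * a$loa_low)
  expect_equal(b$loa_high, 3.7 * a$loa_high)
  expect_error(limits_of_agreement(1), "at least 2")
  expect_equal(tidy(a)$n, 50)
})

test_that("ICC(2,1) matches an explicit ANOVA decomposition and its edge cases", {
  X <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  got <- icc_two_way_random(X)
  expect_equal(got$icc, oracle_icc21(X), tolerance = 1e-12)
  expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)

  # perfect agreement
  Y <- cbind(1:6, 1:6)
  expect_equal(icc_two_way_random(Y)$icc, 1)

  # independent raters at large n: ICC near zero
  set.seed(5)
  Z <- cbind(stats::rnorm(500), stats::rnorm(500))
  expect_lt(abs(icc_two_way_random(Z)$icc), 0.1)

  # zero total variance: undefined, reported missing
  expect_true(is.na(icc_two_way_random(cbind(rep(2, 4), rep(2, 4)))$icc))

  # long format and incomplete cases
  df <- tibble::tibble(case = rep(1:5, each = 2), rater = rep(1:2, 5),
                       value = c(1, 2, 3, 4, 5, 6, 7, 8, 9, NA))
  got_df <- icc_two_way_random(df)
  expect_equal(got_df$n, 4L)   # the case with a missing rater is dropped
  expect_equal(got_df$icc,
               oracle_icc21(cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))),
               tolerance = 1e-12)

  # average-measures form dominates the single-measure form
  g1 <- icc_two_way_random(X)
  gk <- icc_two_way_random(X, type = "agreement_k")
  expect_gt(gk$icc, g1$icc)
  expect_error(icc_two_way_random(X[1, , drop = FALSE]), "at least 2")
})

test_that("ICC recovers simulated variance components", {
  set.seed(23)
  n <- 600
  case <- stats::rnorm(n, 0, 10)
  X <- cbind(case + stats::rnorm(n, 0, 4), case + stats::rnorm(n, 0, 4))
  expected <- 100 / (100 + 16)
  got <- icc_two_way_random(X)$icc
  expect_lt(abs(got - expected), 0.05)
})

test_that("empirical AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(2, 8), rep(0:1, 4))$auc, 0.5)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc,
               oracle_auc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)))
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(stats::runif(n, 0, 10) * 2) / 2   # forces ties
    labels <- stats::runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(r$curve$tpr[nrow(r$curve)], 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "class")
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(41)
  scores <- stats::rnorm(60)
  labels <- stats::runif(60) < 0.3
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(scores^3 + 5 * scores, labels)$auc, a)
  # orientation flip: lower-is-worse on negated scores gives the same AUC
  expect_equal(roc_auc(-scores, labels, direction = "lower_worse")$auc, a)
})

test_that("AUC and its DeLong interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  scores <- stats::rnorm(80)
  labels <- as.integer(stats::runif(80) < 0.35 + 0.3 * (scores > 0))
  r <- roc_auc(scores, labels)
  pr <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(r$ci_high, ci[3], tolerance = 1e-6)
})

test_that("the paired AUC comparison behaves like DeLong's test", {
  set.seed(53)
  sig <- stats::rnorm(100)
  labels <- stats::runif(100) < stats::plogis(sig)
  if (!any(labels)) labels[1] <- TRUE
  a <- sig + stats::rnorm(100, 0, 0.8)
  b <- sig + stats::rnorm(100, 0, 0.8)

  same <- compare_auc_paired(a, a, labels)
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)
  mono <- compare_auc_paired(a, exp(a), labels)
  expect_equal(mono$diff, 0)
  expect_equal(mono$p_value, 1)

  got <- compare_auc_paired(a, b, labels)
  skip_if_not_installed("pROC")
  ra <- pROC::roc(as.integer(labels), a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(as.integer(labels), b, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(compare_auc_paired(a, b[1:10], labels), "equal-length")
})

test_that("the AUROC table orients each measure so signal gives AUC above one half", {
  co <- generate_cohort(cohort_spec(n_kidneys = 160, seed = 61,
                                    ref_midpoint = 50, ref_slope = 6))
  kr <- kidney_results(co)
  kr$label <- resolve_reference(kr$cer, kr$ctest)
  tab <- auroc_table(kr)
  expect_true(all(c("min_d", "min_a", "dred", "ared") %in% tab$measure))
  expect_true(all(tab$auc > 0.5))   # all four orientations carry signal
  expect_true(all(tab$ci_low <= tab$auc & tab$auc <= tab$ci_high))
})

test_that("agreement bundles limits of agreement with the ICC", {
  set.seed(71)
  truth <- stats::rnorm(80, 50, 15)
  x <- truth + stats::rnorm(80, 0, 3)
  y <- truth + stats::rnorm(80, 0, 3)
  ag <- agreement(x, y)
  td <- tidy(ag)
  expect_equal(td$n, 80)
  expect_true(td$loa_low < td$mean_difference &
                td$mean_difference < td$loa_high)
  expect_gt(td$icc, 0.8)
})
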