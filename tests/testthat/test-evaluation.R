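test_that("AUC equals Mann-Whitney concordance with midrank ties", {
  # all scores identical: every pair ties -> 0.5
  expect_equal(auc(rep(1, 10), c(rep(1, 3), rep(0, 7)))$auc, 0.5)

  # perfect separation -> 1 with degenerate CI
  a <- auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))
  expect_equal(a$auc, 1)
  expect_equal(a$ci_low, 1)

  # worked pair count: cases {0.9, 0.4}, controls {0.5, 0.3, 0.1}
  a <- auc(c(0.9, 0.4, 0.5, 0.3, 0.1), c(1, 1, 0, 0, 0))
  expect_equal(a$auc, 5 / 6)

  expect_error(auc(1:5, rep(1, 5)), "at least one")
})

test_that("AUC matches brute-force pairwise concordance on random tied inputs", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    scores <- sample(1:8, n, replace = TRUE) +
      ifelse(runif(n) < 0.5, 0, runif(n))
    outcomes <- rbinom(n, 1, 0.3)
    if (sum(outcomes) %in% c(0, n)) next
    expect_equal(auc(scores, outcomes)$auc,
                 brute_force_auc(scores, outcomes), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:10) {
    n <- 150
    y <- rbinom(n, 1, 0.3)
    s <- rnorm(n, mean = y)
    ours <- auc(s, y)
    theirs <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE, direction = "<"),
                           method = "delong")
    expect_equal(ours$auc, as.numeric(theirs[2]), tolerance = 1e-10)
    expect_equal(ours$ci_low, as.numeric(theirs[1]), tolerance = 1e-6)
    expect_equal(ours$ci_high, as.numeric(theirs[3]), tolerance = 1e-6)
  }
})

test_that("Harrell's C matches exhaustive pair enumeration", {
  expect_error(harrell_c(1:4, c(1, 2, 3, 4), c(0, 0, 0, 0)), "no events")

  # uncensored, scores perfectly rank-aligned with hazard
  t <- c(1, 2, 3, 4, 5); s <- c(9, 7, 5, 3, 1)
  expect_equal(harrell_c(s, t, rep(1, 5))$c, 1)

  # 4-record worked set with one censored record
  s4 <- c(2.0, 1.5, 3.0, 0.5)
  t4 <- c(2, 4, 3, 6)
  e4 <- c(1, 0, 1, 0)
  expect_equal(harrell_c(s4, t4, e4)$c, brute_force_harrell(s4, t4, e4))

  set.seed(33)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    s <- round(rnorm(n), 1)            # induce some score ties
    t <- rexp(n)
    e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) next
    expect_equal(harrell_c(s, t, e)$c, brute_force_harrell(s, t, e),
                 tolerance = 1e-12)
  }
})

test_that("threshold metrics honour the flagged fraction exactly", {
  # 20 records, both events ranked top, q = 0.1 -> flag 2
  scores <- c(10, 9, seq(8, 0.5, length.out = 18))
  outcomes <- c(1, 1, rep(0, 18))
  tm <- threshold_metrics(scores, outcomes, 0.1)
  expect_equal(tm$n_flagged, 2)
  expect_equal(tm$tp, 2); expect_equal(tm$fp, 0)
  expect_equal(tm$sensitivity, 100); expect_equal(tm$ppv, 100)

  # boundary q = 1: everyone flagged
  tm1 <- threshold_metrics(scores, outcomes, 1)
  expect_equal(tm1$sensitivity, 100)
  expect_equal(tm1$specificity, 0)
  expect_equal(tm1$ppv, 100 * mean(outcomes))

  expect_error(threshold_metrics(1:4, c(1, 0, 0, 0), 0.1), "q \\* n < 1")

  # heavy ties still flag exactly round(q * n), and identities hold
  set.seed(55)
  for (i in 1:50) {
    n <- sample(30:200, 1)
    s <- sample(0:5, n, replace = TRUE)    # point-score style ties
    y <- rbinom(n, 1, 0.2)
    q <- sample(c(0.1, 0.2, 0.8, 0.9), 1)
    tm <- threshold_metrics(s, y, q)
    expect_equal(tm$n_flagged, round(q * n))
    expect_equal(tm$tp + tm$fn, sum(y))
    expect_equal(tm$tn + tm$fp, sum(y == 0))
    expect_equal(tm$lr_plus, tm$sensitivity / (100 - tm$specificity))
    # NPV lower bound at prevalence p and achieved unflagged fraction
    p <- mean(y); qa <- tm$n_flagged / n
    if (qa < 1) expect_gte(tm$npv + 1e-9, 100 * (1 - p / (1 - qa)))
  }
})

test_that("specificity follows the confusion-matrix identity at q = 0.1", {
  set.seed(66)
  n <- 2000                                 # divisible by 10
  s <- rnorm(n); y <- rbinom(n, 1, 0.05)
  tm <- threshold_metrics(s, y, 0.1)
  p <- mean(y); sens <- tm$sensitivity / 100
  expect_equal(tm$specificity / 100, (0.9 - p + p * sens) / (1 - p),
               tolerance = 1e-12)
})

test_that("confusion reconstruction from printed summaries is self-consistent", {
  set.seed(77)
  s <- rnorm(500); y <- rbinom(500, 1, 0.1)
  tm <- threshold_metrics(s, y, 0.2)
  back <- confusion_from_summary(tm$sensitivity, tm$specificity, tm$n,
                                 tm$tp + tm$fn)
  expect_equal(back$tp, tm$tp); expect_equal(back$tn, tm$tn)
  expect_equal(back$ppv, tm$ppv); expect_equal(back$lr_minus, tm$lr_minus)
})

test_that("calibration table and Hosmer-Lemeshow match hand computation", {
  # observed equals expected in every group -> chi2 = 0, p = 1
  pred <- rep(c(0.1, 0.2, 0.3, 0.4), each = 50)
  obs <- unlist(lapply(c(0.1, 0.2, 0.3, 0.4), function(p)
    c(rep(1, p * 50), rep(0, 50 - p * 50))))
  cal <- calibration_table(pred, obs, g = 4)
  expect_equal(cal$hl_chi2, 0)
  expect_equal(cal$hl_p, 1)
  expect_equal(sum(cal$groups$n), 200)

  # two-group hand computation: 25/9 + 25/21
  pred2 <- c(rep(0.1, 100), rep(0.3, 100))
  obs2 <- c(rep(1, 15), rep(0, 85), rep(1, 25), rep(0, 75))
  cal2 <- calibration_table(pred2, obs2, g = 2)
  expect_equal(cal2$hl_chi2, 25 / 9 + 25 / 21, tolerance = 1e-12)
  expect_equal(round(cal2$hl_chi2, 4), 3.9683)
  expect_equal(cal2$hl_df, 2)
  expect_equal(cal2$hl_p, pchisq(25 / 9 + 25 / 21, 2, lower.tail = FALSE))

  # uniformly inflating predictions on calibrated data raises chi2
  cal_inflated <- calibration_table(pmin(1, 2 * pred), obs, g = 4)
  expect_gt(cal_inflated$hl_chi2, cal$hl_chi2)

  # group sizes differ by at most 1 when predictions are all distinct
  set.seed(88)
  p <- runif(107)
  y <- rbinom(107, 1, p)
  cal3 <- calibration_table(p, y, g = 10)
  expect_lte(diff(range(cal3$groups$n)), 1)
  expect_equal(sum(cal3$groups$n), 107)

  # degenerate group risk errors
  expect_error(calibration_table(rep(0, 20), rbinom(20, 1, 0.1)),
               "exactly 0 or 1")
})

test_that("age-threshold screening sensitivity matches manual counts", {
  coh <- data.frame(
    age = c(62, 55, 70, 48, 66, 59, 61, 52),
    sex = c("male", "male", "female", "female", "male", "female", "male",
            "female"),
    event = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  res <- age_rule_sensitivity(coh, 60)
  ov <- res[res$stratum == "overall", ]
  # events at ages 62, 55, 70, 59 -> 2 of 4 are >= 60
  expect_equal(ov$sensitivity, 50)
  expect_equal(ov$flagged_fraction, 4 / 8)
  expect_equal(res[res$stratum == "male", "sensitivity"], 50)

  expect_equal(age_rule_sensitivity(coh, 10)[1, "sensitivity"], 100)
  expect_equal(age_rule_sensitivity(coh, 99)[1, "sensitivity"], 0)
})
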