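test_that("well-formed specs validate and malformed specs are rejected", {
  expect_s3_class(toy_logistic_spec(), "crc_model_spec")

  # cox without baseline survival
  expect_error(
    model_spec("bad-cox", form = "cox", native_horizon_years = 10,
               mean_linear_predictor = 0,
               covariates = list(covariate_def("age", "continuous")),
               terms = list(term_spec("age", 0.05))),
    "baseline_survival")

  # non-monotone points map (pairwise comparison)
  bad_map <- data.frame(points = c(0, 5), risk = c(0.01, 0.005))
  expect_true(any(diff(bad_map$risk) < 0))
  expect_error(
    model_spec("bad-points", form = "points", native_horizon_years = 10,
               points_to_risk = bad_map,
               covariates = list(covariate_def("age", "continuous")),
               terms = list(term_spec("age", 1,
                                      transform = list(list(indicator = 60))))),
    "non-decreasing")

  # term on an undeclared covariate
  expect_error(
    model_spec("bad-term", form = "logistic", native_horizon_years = 5,
               intercept = -5,
               covariates = list(covariate_def("age", "continuous")),
               terms = list(term_spec("bmi", 0.1))),
    "unknown covariate")

  # categorical term without a level; continuous term with one
  expect_error(
    model_spec("bad-level", form = "logistic", native_horizon_years = 5,
               intercept = -5,
               covariates = list(covariate_def("smoking", "categorical",
                                               levels = c("never", "ever"),
                                               reference_level = "never")),
               terms = list(term_spec("smoking", 0.3))),
    "needs a level")
  expect_error(
    model_spec("bad-level2", form = "logistic", native_horizon_years = 5,
               intercept = -5,
               covariates = list(covariate_def("age", "continuous")),
               terms = list(term_spec("age", 0.1, level = "x"))),
    "must not carry a level")

  # baseline fields not demanded by the form are rejected
  expect_error(
    model_spec("extra", form = "logistic", native_horizon_years = 5,
               intercept = -5, baseline_risk = 0.01,
               covariates = list(), terms = list()),
    "must not carry")
})

test_that("linear predictor matches hand evaluation", {
  spec <- toy_logistic_spec()
  rec <- data.frame(age = 60, sex = "male", smoking = "never")
  # 0.08 * (60 - 40) + 0.4 = 2.0
  expect_equal(linear_predictor(spec, rec), 2.0)

  # all-zero coefficients give zero
  zspec <- spec
  for (i in seq_along(zspec$terms)) zspec$terms[[i]]$coefficient <- 0
  expect_equal(linear_predictor(zspec, rec), 0)

  # points record matching no scored level gives zero points
  prec <- data.frame(age = 50, smoking = "never")
  expect_equal(linear_predictor(toy_points_spec(), prec), 0)

  # missing covariate value propagates to NA
  mrec <- data.frame(age = 60, sex = "male", smoking = NA_character_)
  expect_true(is.na(linear_predictor(spec, mrec)))
})

test_that("absolute risk follows each functional form", {
  # cox at the mean linear predictor gives exactly 1 - S0
  cx <- toy_cox_spec(s0 = 0.99, mean_lp = 0)
  rec <- data.frame(age = 50, bmi = 25)   # lp = 0 = mean
  expect_equal(absolute_risk(cx, rec), 0.01)

  # logistic with intercept + lp = -4: independent inverse-logit
  lg <- model_spec("l", form = "logistic", native_horizon_years = 5,
                   intercept = -4, covariates = list(), terms = list())
  expect_equal(absolute_risk(lg, data.frame(x = 1)),
               exp(-4) / (1 + exp(-4)), tolerance = 1e-12)
  expect_equal(round(absolute_risk(lg, data.frame(x = 1)), 6), 0.017986)

  # rr_product with all relative risks 1 returns the baseline
  rr <- toy_rr_spec(baseline = 0.005)
  rec <- data.frame(family_history = FALSE, red_meat = "<3 times/week")
  expect_equal(absolute_risk(rr, rec), 0.005)
  # and is capped at 1
  rr_big <- toy_rr_spec(baseline = 0.9)
  rec2 <- data.frame(family_history = TRUE, red_meat = ">=3 times/week")
  expect_lte(absolute_risk(rr_big, rec2), 1)

  # points lookup is a step function of the point total
  ps <- toy_points_spec()
  expect_equal(absolute_risk(ps, data.frame(age = 60, smoking = "current")),
               0.012)  # 2 + 3 = 5 points -> threshold 4
  expect_equal(absolute_risk(ps, data.frame(age = 50, smoking = "never")),
               0.002)
})

test_that("risks stay in [0,1] and increase with any coefficient-value product", {
  set.seed(42)
  for (rep in 1:20) {
    b <- rnorm(1)
    spec <- if (rep %% 2)
      model_spec("m", form = "logistic", native_horizon_years = 5,
                 intercept = rnorm(1),
                 covariates = list(covariate_def("x", "continuous")),
                 terms = list(term_spec("x", abs(b))))
    else
      model_spec("m", form = "cox", native_horizon_years = 5,
                 baseline_survival = runif(1, 0.8, 0.999),
                 mean_linear_predictor = rnorm(1),
                 covariates = list(covariate_def("x", "continuous")),
                 terms = list(term_spec("x", abs(b))))
    xs <- sort(rnorm(10))
    r <- absolute_risk(spec, data.frame(x = xs))
    expect_true(all(r >= 0 & r <= 1))
    expect_true(all(diff(r) >= 0))
  }
})

test_that("applicability flags sex and age without blocking", {
  cx <- toy_cox_spec()   # male-only
  cx$applicable_age_range <- c(50, 89)
  cx <- validate_model_spec(cx)

  coh <- data.frame(age = c(45, 60, 60), sex = c("male", "male", "female"),
                    bmi = 25)
  app <- applicability(cx, coh)
  expect_equal(as.logical(app), c(FALSE, TRUE, FALSE))
  expect_equal(attr(app, "age_ok"), c(FALSE, TRUE, TRUE))
  expect_equal(attr(app, "sex_ok"), c(TRUE, TRUE, FALSE))

  # no declared age range: vacuously age-applicable
  cx2 <- toy_cox_spec()
  app2 <- applicability(cx2, coh)
  expect_true(all(attr(app2, "age_ok")))

  # the female record can still be scored despite the sex flag
  expect_false(is.na(linear_predictor(cx, coh[3, , drop = FALSE])))
})

test_that("drop_terms is exact and additive", {
  spec <- toy_logistic_spec()
  expect_identical(drop_terms(spec, character()), spec)
  expect_error(drop_terms(spec, "deprivation"), "no term")

  rec <- data.frame(age = 60, sex = "male", smoking = "current")
  lp_full <- linear_predictor(spec, rec)
  dropped <- drop_terms(spec, "sex")
  # dropping a present binary-indicator term lowers lp by exactly beta
  expect_equal(lp_full - linear_predictor(dropped, rec), 0.4)
  # additivity: scoring the reduced spec equals subtracting the term
  cohort <- data.frame(age = runif(50, 40, 70),
                       sex = sample(c("male", "female"), 50, TRUE),
                       smoking = sample(c("never", "former", "current"),
                                        50, TRUE))
  expect_equal(linear_predictor(dropped, cohort),
               linear_predictor(spec, cohort) -
                 0.4 * (cohort$sex == "male"))
})

test_that("spec files round-trip through JSON and YAML", {
  specs <- list(toy_logistic_spec(), toy_cox_spec(), toy_points_spec(),
                toy_rr_spec())
  for (spec in specs) {
    for (ext in c("json", "yaml")) {
      f <- tempfile(fileext = paste0(".", ext))
      write_model_spec(spec, f)
      back <- read_model_spec(f)
      expect_equal(back, spec, ignore_attr = FALSE)
      unlink(f)
    }
  }
})
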