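# Synthetic fixture specs and toy cohorts built in code. None of these
# reproduce any published model's coefficients.

toy_logistic_spec <- function() {
  model_spec(
    model_id = "toy-logistic", form = "logistic", native_horizon_years = 5,
    intercept = -6,
    covariates = list(
      covariate_def("age", "continuous", unit = "years"),
      covariate_def("sex", "categorical", levels = c("female", "male"),
                    reference_level = "female"),
      covariate_def("smoking", "categorical",
                    levels = c("never", "former", "current"),
                    reference_level = "never")),
    terms = list(
      term_spec("age", 0.08, transform = list(list(center = 40))),
      term_spec("sex", 0.4, level = "male"),
      term_spec("smoking", 0.3, level = "current")))
}

toy_cox_spec <- function(s0 = 0.99, mean_lp = 1.2) {
  model_spec(
    model_id = "toy-cox", form = "cox", native_horizon_years = 10,
    baseline_survival = s0, mean_linear_predictor = mean_lp,
    covariates = list(
      covariate_def("age", "continuous"),
      covariate_def("bmi", "continuous")),
    terms = list(
      term_spec("age", 0.05, transform = list(list(center = 50))),
      term_spec("bmi", 0.03, transform = list(list(center = 25)))),
    applicable_sexes = "male")
}

toy_points_spec <- function() {
  model_spec(
    model_id = "toy-points", form = "points", native_horizon_years = 10,
    points_to_risk = data.frame(points = c(0, 2, 4, 6),
                                risk = c(0.002, 0.005, 0.012, 0.03)),
    covariates = list(
      covariate_def("age", "continuous"),
      covariate_def("smoking", "categorical",
                    levels = c("never", "former", "current"),
                    reference_level = "never")),
    terms = list(
      term_spec("age", 2, transform = list(list(indicator = 60))),
      term_spec("smoking", 1, level = "former"),
      term_spec("smoking", 3, level = "current")))
}

toy_rr_spec <- function(baseline = 0.005) {
  model_spec(
    model_id = "toy-rr", form = "rr_product", native_horizon_years = 10,
    baseline_risk = baseline,
    covariates = list(
      covariate_def("family_history", "binary"),
      covariate_def("red_meat", "categorical",
                    levels = c("<3 times/week", ">=3 times/week"),
                    reference_level = "<3 times/week")),
    terms = list(
      term_spec("family_history", log(1.8)),
      term_spec("red_meat", log(1.2), level = ">=3 times/week")))
}

toy_cohort <- function() {
  data.frame(
    participant_id = sprintf("T%02d", 1:6),
    age = c(60, 45, 52, 70, 58, 63),
    sex = c("male", "female", "male", "female", "male", "female"),
    smoking = c("never", "current", "former", NA, "never", "former"),
    bmi = c(27, 22, NA, 31, 25, 28),
    family_history = c(TRUE, FALSE, FALSE, TRUE, NA, FALSE),
    red_meat = c(">=3 times/week", "<3 times/week", "<3 times/week",
                 ">=3 times/week", "<3 times/week", "<3 times/week"),
    prior_diagnosis_codes = c("", "C18.4", "", "K63.5", "", ""),
    death_before_baseline = FALSE,
    followup_years = c(6.1, 5.5, 3.2, 7.0, 5.0, 6.5),
    censor_reason = c(NA, NA, "death", NA, NA, NA),
    event = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    event_subtype = c("colon", NA, NA, "rectal", NA, NA),
    event_time_years = c(3.4, NA, NA, 4.8, NA, NA),
    stringsAsFactors = FALSE)
}

# Brute-force pairwise AUC: mean over all case-control pairs, ties = 1/2.
brute_force_auc <- function(scores, outcomes) {
  s1 <- scores[outcomes == 1]; s0 <- scores[outcomes == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive-pair Harrell's C: pairs comparable when the shorter time is
# an event; score ties count one half.
brute_force_harrell <- function(scores, time, event) {
  n <- length(scores); num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    shorter <- if (time[i] < time[j]) i else j
    longer <- if (shorter == i) j else i
    if (!event[shorter]) next
    den <- den + 1
    if (scores[shorter] > scores[longer]) num <- num + 1
    else if (scores[shorter] == scores[longer]) num <- num + 0.5
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
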