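#' Area under the ROC curve with DeLong confidence interval
#'
#' Mann-Whitney concordance: the probability that a randomly chosen case
#' scores higher than a randomly chosen non-case, with midrank handling of
#' ties (tied pairs count one half). The confidence interval uses the
#' DeLong placement-variance estimator, the standard choice for external
#' validation studies; `ci_method = "hanley"` falls back to the
#' Hanley-McNeil variance for very small samples.
#'
#' @param scores Numeric risk scores (any monotone scale).
#' @param outcomes Binary outcome vector (0/1 or logical).
#' @param conf_level Confidence level, default 0.95.
#' @param ci_method `"delong"` (default) or `"hanley"`.
#' @return An object of class `crc_discrimination`: list with `auc`,
#'   `ci_low`, `ci_high`, `se`, `n`, `n_events`.
#' @export
auc <- function(scores, outcomes, conf_level = 0.95,
                ci_method = c("delong", "hanley")) {
  ci_method <- match.arg(ci_method)
  outcomes <- as.integer(as.logical(outcomes))
  ok <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[ok]; outcomes <- outcomes[ok]
  n1 <- sum(outcomes == 1L); n0 <- sum(outcomes == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("auc needs at least one event and one non-event")

  r <- rank(scores)                       # midranks
  a <- (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  if (ci_method == "delong") {
    # placements: V10_i = P(control < case_i) + .5 P(tie), via midranks
    r1 <- rank(scores[outcomes == 1L])
    r0 <- rank(scores[outcomes == 0L])
    v10 <- (r[outcomes == 1L] - r1) / n0
    v01 <- 1 - (r[outcomes == 0L] - r0) / n1
    var_a <- stats::var(v10) / n1 + stats::var(v01) / n0
    if (is.na(var_a)) var_a <- 0        # single case or control
  } else {
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    var_a <- (a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                (n0 - 1) * (q2 - a^2)) / (n1 * n0)
  }
  se <- sqrt(max(0, var_a))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = a, ci_low = max(0, a - z * se),
                 ci_high = min(1, a + z * se), se = se,
                 n = n1 + n0, n_events = n1, ci_method = ci_method,
                 conf_level = conf_level),
            class = "crc_discrimination")
}

#' @export
print.crc_discrimination <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f), n = %d, events = %d\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n, x$n_events))
  invisible(x)
}

#' Harrell's C for censored follow-up
#'
#' Concordance over comparable pairs — pairs in which the participant with
#' the shorter follow-up time experienced the event — with score ties
#' counting one half. Used for the open-cohort analysis, where
#' participants with under five years of follow-up are retained and
#' censoring must be accounted for. Computation is delegated to
#' [survival::concordance()] (O(n log n)); an exhaustive pair-enumeration
#' definition is the reference in this package's test suite.
#'
#' @param scores Numeric risk scores (higher = higher predicted risk).
#' @param time Follow-up times.
#' @param event Event indicator (1/TRUE = event at `time`).
#' @return List with `c` (the concordance), `se`, `n`, `n_events`,
#'   `comparable` (number of comparable pairs).
#' @export
harrell_c <- function(scores, time, event) {
  event <- as.integer(as.logical(event))
  ok <- !is.na(scores) & !is.na(time) & !is.na(event)
  scores <- scores[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) == 0L) stop("no events: no comparable pairs")
  fit <- survival::concordance(survival::Surv(time, event) ~ scores,
                               reverse = TRUE, timefix = FALSE)
  counts <- fit$count
  comparable <- sum(counts[c("concordant", "discordant", "tied.x")])
  if (comparable == 0) stop("no comparable pairs")
  list(c = as.numeric(fit$concordance), se = sqrt(as.numeric(fit$var)),
       n = length(scores), n_events = sum(event), comparable = comparable)
}

#' Threshold metrics at a top-q flagging cutoff
#'
#' Emulates risk-stratified screening at a population cutoff: the
#' fraction `q` of the population with the highest scores is flagged, and
#' the confusion matrix against the binary 5-year outcome yields
#' sensitivity, specificity, likelihood ratios and predictive values.
#' The cutoff is the empirical `1 - q` quantile; ties at the cutoff are
#' resolved in stable participant order so that exactly `round(q * n)`
#' participants are flagged even for heavily tied point scores.
#'
#' @param scores Numeric risk scores.
#' @param outcomes Binary outcome vector.
#' @param q Flagged fraction in (0, 1]; `q = 1` (flag everyone) is allowed
#'   as a boundary case.
#' @return An object of class `crc_threshold_metrics`: list with `q`,
#'   `cutoff`, counts `tp`, `fp`, `tn`, `fn`, and `sensitivity`,
#'   `specificity`, `ppv`, `npv` (all in percent), `lr_plus`, `lr_minus`.
#' @export
threshold_metrics <- function(scores, outcomes, q) {
  outcomes <- as.integer(as.logical(outcomes))
  stopifnot(length(scores) == length(outcomes))
  n <- length(scores)
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  m <- round(q * n)
  if (m < 1) stop("q * n < 1: cannot flag a fraction smaller than one record")
  ord <- order(scores, decreasing = TRUE)    # stable for ties
  flagged <- logical(n)
  flagged[ord[seq_len(m)]] <- TRUE
  cutoff <- scores[ord[m]]

  tp <- sum(flagged & outcomes == 1L)
  fp <- sum(flagged & outcomes == 0L)
  fn <- sum(!flagged & outcomes == 1L)
  tn <- sum(!flagged & outcomes == 0L)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  structure(list(
    q = q, cutoff = cutoff, n = n, n_flagged = m,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec,
    lr_plus = sens / (100 - spec), lr_minus = (100 - sens) / spec,
    ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn)),
    class = "crc_threshold_metrics")
}

#' @export
print.crc_threshold_metrics <- function(x, ...) {
  cat(sprintf(
    "Top %.0f%%: sens %.1f  spec %.1f  LR+ %.2f  LR- %.2f  PPV %.1f%%  NPV %.1f%%\n",
    100 * x$q, x$sensitivity, x$specificity, x$lr_plus, x$lr_minus,
    x$ppv, x$npv))
  invisible(x)
}

#' Reconstruct threshold metrics from printed summary values
#'
#' Published validation tables report sensitivity, specificity, total n
#' and event count; the confusion matrix — and hence likelihood ratios and
#' predictive values — is algebraically determined by those four numbers.
#' This helper rebuilds it, allowing internal-consistency checks of
#' printed tables. Counts are generally non-integer because the printed
#' inputs are rounded.
#'
#' @param sensitivity,specificity In percent.
#' @param n Total sample size.
#' @param n_events Number of events.
#' @return A list shaped like [threshold_metrics()] output (without
#'   `q`/`cutoff`).
#' @export
confusion_from_summary <- function(sensitivity, specificity, n, n_events) {
  tp <- sensitivity / 100 * n_events
  fn <- n_events - tp
  tn <- specificity / 100 * (n - n_events)
  fp <- (n - n_events) - tn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sensitivity, specificity = specificity,
       lr_plus = sensitivity / (100 - specificity),
       lr_minus = (100 - sensitivity) / specificity,
       ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn))
}

#' Decile calibration table with Hosmer-Lemeshow statistic
#'
#' Groups participants into `g` equal-count groups of predicted risk
#' (ties kept together), compares observed event counts with expected
#' counts, and summarises with the Hosmer-Lemeshow chi-square
#' `sum((O - E)^2 / (E * (1 - pbar)))`. Degrees of freedom equal the
#' number of groups: in external validation no parameters are estimated
#' on the data, so the g - 2 convention of the development setting does
#' not apply.
#'
#' @param pred_5y Predicted 5-year risks in `[0, 1]`.
#' @param outcomes Binary outcome vector.
#' @param g Number of groups (default 10, i.e. deciles).
#' @return An object of class `crc_calibration`: list with `groups`
#'   (data frame: `group`, `n`, `mean_predicted`, `observed_events`,
#'   `observed_proportion`), `hl_chi2`, `hl_df`, `hl_p`.
#' @export
calibration_table <- function(pred_5y, outcomes, g = 10) {
  outcomes <- as.integer(as.logical(outcomes))
  ok <- !is.na(pred_5y) & !is.na(outcomes)
  pred_5y <- pred_5y[ok]; outcomes <- outcomes[ok]
  if (any(pred_5y < 0 | pred_5y > 1)) stop("predictions must lie in [0, 1]")
  n <- length(pred_5y)
  # rank-based equal-count grouping; tied predictions share a group
  grp <- ceiling(g * rank(pred_5y, ties.method = "min") / n)
  grp <- match(grp, sort(unique(grp)))       # renumber 1..G
  G <- max(grp)
  tab <- data.frame(
    group = seq_len(G),
    n = as.integer(tabulate(grp, G)),
    mean_predicted = as.numeric(tapply(pred_5y, grp, mean)),
    observed_events = as.integer(tapply(outcomes, grp, sum)))
  tab$observed_proportion <- tab$observed_events / tab$n
  if (any(tab$mean_predicted %in% c(0, 1)))
    stop("a calibration group has mean predicted risk of exactly 0 or 1")
  expected <- tab$n * tab$mean_predicted
  chi2 <- sum((tab$observed_events - expected)^2 /
                (expected * (1 - tab$mean_predicted)))
  structure(list(groups = tab, hl_chi2 = chi2, hl_df = G,
                 hl_p = stats::pchisq(chi2, df = G, lower.tail = FALSE)),
            class = "crc_calibration")
}

#' @export
print.crc_calibration <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow chi2 = %.3f on %d df, p = %.3g\n",
              x$hl_chi2, x$hl_df, x$hl_p))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Sensitivity of an age-threshold screening rule
#'
#' The comparator for risk-stratified flagging: flag everyone at or above
#' a baseline age cutoff (as age-based screening programmes do) and
#' report the sensitivity for incident colorectal cancer together with
#' the flagged fraction, overall and by sex.
#'
#' @param cohort Data frame with `age`, `sex` and `event`.
#' @param age_cutoff Age threshold in years.
#' @return Data frame with rows overall/male/female and columns
#'   `sensitivity` (percent) and `flagged_fraction`.
#' @export
age_rule_sensitivity <- function(cohort, age_cutoff) {
  one <- function(df) {
    flagged <- df$age >= age_cutoff
    ev <- as.logical(df$event)
    data.frame(
      n = nrow(df), n_events = sum(ev),
      sensitivity = if (sum(ev) == 0) NA_real_
        else 100 * sum(flagged & ev) / sum(ev),
      flagged_fraction = mean(flagged))
  }
  out <- rbind(
    cbind(stratum = "overall", one(cohort)),
    cbind(stratum = "male",    one(cohort[cohort$sex == "male", , drop = FALSE])),
    cbind(stratum = "female",  one(cohort[cohort$sex == "female", , drop = FALSE])))
  rownames(out) <- NULL
  out
}
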