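#' Define a covariate derivation rule
#'
#' Derives one model-ready covariate from raw cohort fields. Five
#' combinators cover the harmonization needs of the published models:
#'
#' * `sum` — arithmetic sum of the sources (e.g. red meat = beef + pork +
#'   lamb servings per week);
#' * `any` — logical disjunction (e.g. current NSAID use from either the
#'   regular-medication question or a listed treatment code);
#' * `threshold` — dichotomise one numeric source at `cutoff` into two
#'   labelled categories (below / at-or-above);
#' * `map` — recode one source through a lookup table;
#' * `constant` — fill a fixed value (e.g. a literature-mean medication
#'   duration absent from the raw data).
#'
#' Missingness propagates: any missing source makes the target missing,
#' except under `any`, where a single `TRUE` source suffices.
#'
#' @param target Name of the derived covariate.
#' @param sources Character vector of raw field names (empty for
#'   `constant`).
#' @param combinator One of `"sum"`, `"any"`, `"threshold"`, `"map"`,
#'   `"constant"`.
#' @param cutoff Numeric cutoff (`threshold` only).
#' @param labels Length-2 labels for below / at-or-above the cutoff
#'   (`threshold` only; defaults to `"<cutoff"`, `">=cutoff"`).
#' @param table Named vector mapping source values to target values
#'   (`map` only).
#' @param value Constant value (`constant` only).
#' @return An object of class `crc_derivation_rule`.
#' @export
derivation_rule <- function(target, sources = character(),
                            combinator = c("sum", "any", "threshold",
                                           "map", "constant"),
                            cutoff = NULL, labels = NULL, table = NULL,
                            value = NULL) {
  combinator <- match.arg(combinator)
  if (combinator == "threshold") {
    if (is.null(cutoff) || length(sources) != 1L)
      stop("threshold rule needs exactly one source and a cutoff")
    if (is.null(labels))
      labels <- c(paste0("<", cutoff), paste0(">=", cutoff))
    stopifnot(length(labels) == 2L)
  }
  if (combinator == "map" && (is.null(table) || length(sources) != 1L))
    stop("map rule needs exactly one source and a lookup table")
  if (combinator == "constant" && is.null(value))
    stop("constant rule needs a value")
  if (combinator %in% c("sum", "any") && length(sources) == 0)
    stop(combinator, " rule needs at least one source")
  structure(list(target = target, sources = as.character(sources),
                 combinator = combinator, cutoff = cutoff, labels = labels,
                 table = table, value = value),
            class = "crc_derivation_rule")
}

#' Derive model-ready covariates from raw cohort fields
#'
#' Applies [derivation_rule()]s in order; each rule adds (or overwrites)
#' its target column, so later rules may consume earlier targets.
#'
#' @param raw_cohort Data frame of raw fields.
#' @param rules List of `crc_derivation_rule` objects.
#' @return The cohort with derived columns appended.
#' @export
derive_variables <- function(raw_cohort, rules) {
  for (rule in rules) {
    missing_src <- setdiff(rule$sources, names(raw_cohort))
    if (length(missing_src))
      stop("rule '", rule$target, "': unknown source field(s) ",
           paste(missing_src, collapse = ", "))
    raw_cohort[[rule$target]] <- switch(rule$combinator,
      sum = Reduce(`+`, lapply(rule$sources, function(s)
        as.numeric(raw_cohort[[s]]))),
      any = {
        src <- lapply(rule$sources, function(s) as.logical(raw_cohort[[s]]))
        any_true <- Reduce(`|`, lapply(src, function(v) !is.na(v) & v))
        any_na <- Reduce(`|`, lapply(src, is.na))
        out <- Reduce(`|`, lapply(src, function(v) !is.na(v) & v))
        out[!any_true & any_na] <- NA
        out
      },
      threshold = {
        v <- as.numeric(raw_cohort[[rule$sources]])
        ifelse(is.na(v), NA_character_,
               ifelse(v < rule$cutoff, rule$labels[1], rule$labels[2]))
      },
      map = {
        v <- as.character(raw_cohort[[rule$sources]])
        unname(rule$table[v])
      },
      constant = rep(rule$value, nrow(raw_cohort)))
  }
  raw_cohort
}

#' Apply the cohort-definition exclusions
#'
#' Removes, in order: participants with a prior colorectal-cancer
#' diagnosis code, participants recorded as dead before baseline, and
#' (when `require_5y`) participants without five years of follow-up —
#' unless their follow-up ended by death, who are retained so the closed
#' cohort reflects the clinical use of the scores. Step-by-step removal
#' counts are attached as the `"exclusion_counts"` attribute.
#'
#' @param cohort Data frame with `prior_diagnosis_codes`,
#'   `death_before_baseline`, `followup_years` and optionally
#'   `censor_reason` (`"death"` marks follow-up ended by death).
#' @param prior_crc A `crc_code_set`; defaults to [crc_code_set()].
#' @param require_5y Apply the five-year follow-up requirement (closed
#'   cohort)?
#' @return The retained cohort, with attribute `exclusion_counts`.
#' @export
apply_exclusions <- function(cohort, prior_crc = crc_code_set(),
                             require_5y = TRUE) {
  n0 <- nrow(cohort)
  prior <- if ("prior_diagnosis_codes" %in% names(cohort))
    codes_match(cohort$prior_diagnosis_codes, prior_crc)
  else rep(FALSE, n0)
  cohort <- cohort[!prior, , drop = FALSE]
  n_prior <- n0 - nrow(cohort)

  dead <- if ("death_before_baseline" %in% names(cohort))
    !is.na(cohort$death_before_baseline) & cohort$death_before_baseline
  else rep(FALSE, nrow(cohort))
  cohort <- cohort[!dead, , drop = FALSE]
  n_dead <- sum(dead)

  n_short <- 0L
  if (require_5y) {
    death_censor <- if ("censor_reason" %in% names(cohort))
      !is.na(cohort$censor_reason) & cohort$censor_reason == "death"
    else rep(FALSE, nrow(cohort))
    short <- cohort$followup_years < 5 & !death_censor
    cohort <- cohort[!short, , drop = FALSE]
    n_short <- sum(short)
  }
  rownames(cohort) <- NULL
  attr(cohort, "exclusion_counts") <- c(
    total = n0, prior_crc = n_prior, death_before_baseline = n_dead,
    insufficient_followup = n_short, retained = nrow(cohort))
  cohort
}

#' Exclude participants likely under colonoscopic surveillance
#'
#' Removes participants whose prior diagnosis codes include a colorectal
#' polyp or inflammatory bowel disease code, for the sensitivity analysis
#' in which surveillance-detected cancers are set aside.
#'
#' @param cohort Data frame with `prior_diagnosis_codes`.
#' @param polyp_ibd A `crc_code_set`; defaults to [surveillance_code_set()].
#' @return The retained cohort with attribute `surveillance_removed`.
#' @export
exclude_surveillance <- function(cohort, polyp_ibd = surveillance_code_set()) {
  if (!inherits(polyp_ibd, "crc_code_set"))
    stop("polyp_ibd must be a crc_code_set")
  flagged <- codes_match(cohort$prior_diagnosis_codes, polyp_ibd)
  out <- cohort[!flagged, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "surveillance_removed") <- sum(flagged)
  out
}

#' Complete-case mask for one model
#'
#' `TRUE` for each participant with non-missing values for every covariate
#' referenced by the model's terms. Validation is complete-case on a
#' per-model basis, so the analysable sample size varies between models.
#'
#' @param cohort Data frame of harmonized records.
#' @param spec A validated `crc_model_spec`.
#' @return Logical vector of length `nrow(cohort)`.
#' @export
complete_case_mask <- function(cohort, spec) {
  covs <- unique(vapply(spec$terms, function(t) t$covariate, character(1)))
  if (length(covs) == 0) return(rep(TRUE, nrow(cohort)))
  mask <- rep(TRUE, nrow(cohort))
  for (cn in covs) {
    if (!cn %in% names(cohort)) {
      warning("covariate '", cn, "' absent from cohort; treated as missing")
      return(rep(FALSE, nrow(cohort)))
    }
    mask <- mask & !is.na(cohort[[cn]])
  }
  mask
}

# Nearest-rank percentile of observed (non-missing) values.
nearest_rank_percentile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  x[max(1L, ceiling(p / 100 * length(x)))]
}

#' Extreme-case imputation of heavily missing risk factors
#'
#' For each risk factor whose missing fraction exceeds `threshold_pct`
#' percent, missing values are replaced by an extreme of the observed
#' distribution: the 90th (`direction = "high"`) or 10th
#' (`direction = "low"`) nearest-rank percentile for continuous factors,
#' and present (`TRUE`) or absent (`FALSE`) for dichotomous (logical)
#' factors. Factors at or below the threshold, multi-level categorical
#' factors, and all non-missing values are untouched. Running both
#' directions brackets the possible impact of the missing data.
#'
#' @param cohort Data frame of harmonized records.
#' @param factors Columns to consider; defaults to every column except the
#'   identifier, outcome, follow-up and code-list columns.
#' @param threshold_pct Missingness percentage above which a factor is
#'   imputed (default 5).
#' @param direction `"high"` or `"low"`.
#' @return The cohort with extreme values imputed; attribute
#'   `imputed_factors` lists the factors touched.
#' @export
extreme_value_impute <- function(cohort, factors = NULL, threshold_pct = 5,
                                 direction = c("high", "low")) {
  direction <- match.arg(direction)
  reserved <- c("participant_id", "prior_diagnosis_codes",
                "death_before_baseline", "followup_years", "event",
                "event_subtype", "event_time_years", "censor_reason")
  if (is.null(factors)) factors <- setdiff(names(cohort), reserved)
  p <- if (direction == "high") 90 else 10
  touched <- character()
  for (cn in factors) {
    v <- cohort[[cn]]
    miss <- is.na(v)
    if (100 * mean(miss) <= threshold_pct) next
    if (is.logical(v)) {
      v[miss] <- direction == "high"
    } else if (is.numeric(v)) {
      if (all(miss)) next
      v[miss] <- nearest_rank_percentile(v, p)
    } else {
      next   # multi-level categorical: no defensible extreme
    }
    cohort[[cn]] <- v
    touched <- c(touched, cn)
  }
  attr(cohort, "imputed_factors") <- touched
  cohort
}
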