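#' Configuration for a validation run
#'
#' Bundles everything [run_validation()] needs: the models, the cohort,
#' the cohort design, the hazard assumptions under which horizon
#' conversion is performed, the flagging fractions for threshold metrics,
#' and the sensitivity-analysis toggles consumed by
#' [sensitivity_battery()].
#'
#' @param models List of `crc_model_spec` objects, or paths to spec files.
#' @param cohort Data frame of participant records, or a CSV path.
#' @param cohort_mode `"closed"` (binary outcome at 5 years; 5-year
#'   follow-up required except for deaths) or `"open"` (censored
#'   follow-up retained; discrimination by Harrell's C).
#' @param assumptions List of [hazard_assumption()]s to run calibration
#'   under.
#' @param q Flagging fractions for [threshold_metrics()].
#' @param outcome_scope `"CRC"` or `"colon"` (restricts events to the
#'   colon subtype).
#' @param sensitivity Named list of toggles: logical
#'   `extreme_impute_high`, `extreme_impute_low`, `exclude_surveillance`,
#'   `open_cohort`, and `drop_term_sets`, a named list of covariate-name
#'   vectors to drop per set.
#' @param derivation_rules Optional list of [derivation_rule()]s applied
#'   to the cohort before scoring.
#' @param seed Integer recorded in provenance (the validation itself is
#'   deterministic).
#' @param output_dir Optional directory for [write_report()].
#' @return An object of class `crc_run_config`.
#' @export
run_config <- function(models, cohort,
                       cohort_mode = c("closed", "open"),
                       assumptions = list(hazard_assumption("constant"),
                                          hazard_assumption("doubling")),
                       q = c(0.10, 0.20, 0.80, 0.90),
                       outcome_scope = c("CRC", "colon"),
                       sensitivity = list(),
                       derivation_rules = NULL,
                       seed = 1L, output_dir = NULL) {
  cohort_mode <- match.arg(cohort_mode)
  outcome_scope <- match.arg(outcome_scope)
  if (length(models) == 0) stop("at least one model is required")
  if (any(q <= 0 | q >= 1)) stop("q values must lie in (0, 1)")
  known <- c("extreme_impute_high", "extreme_impute_low", "drop_term_sets",
             "exclude_surveillance", "open_cohort")
  unknown <- setdiff(names(sensitivity), known)
  if (length(unknown))
    stop("unknown sensitivity toggle(s): ", paste(unknown, collapse = ", "))
  structure(list(models = models, cohort = cohort,
                 cohort_mode = cohort_mode, assumptions = assumptions,
                 q = q, outcome_scope = outcome_scope,
                 sensitivity = sensitivity,
                 derivation_rules = derivation_rules,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "crc_run_config")
}

load_models <- function(models) {
  specs <- lapply(models, function(m)
    if (inherits(m, "crc_model_spec")) m else read_model_spec(m))
  names(specs) <- vapply(specs, function(s) s$model_id, character(1))
  specs
}

config_hash <- function(config) {
  # md5 of a canonical JSON rendering (model ids, not file paths)
  canon <- list(
    models = sort(names(load_models(config$models))),
    cohort_mode = config$cohort_mode,
    assumptions = lapply(config$assumptions, unclass),
    q = config$q, outcome_scope = config$outcome_scope,
    sensitivity = config$sensitivity, seed = config$seed)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(canon, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

# Binary 5-year outcome under the configured scope.
outcome_at_5y <- function(cohort, outcome_scope) {
  ev <- as.logical(cohort$event) & !is.na(cohort$event_time_years) &
    cohort$event_time_years <= 5
  if (outcome_scope == "colon")
    ev <- ev & !is.na(cohort$event_subtype) & cohort$event_subtype == "colon"
  ev
}

assumption_label <- function(a)
  if (a$shape == "doubling")
    paste0("doubling_", a$doubling_period_years, "y") else "constant"

# Evaluate one model in one sex stratum.
evaluate_stratum <- function(sub, y, lp, risk_5y_by_assumption, config) {
  n1 <- sum(y); n0 <- sum(!y)
  disc <- NULL; hc <- NULL
  if (config$cohort_mode == "closed") {
    if (n1 > 0 && n0 > 0) disc <- auc(lp, y)
  } else {
    if (sum(sub$event) > 0)
      hc <- harrell_c(lp, sub$followup_years, as.logical(sub$event))
  }
  thresh <- NULL
  if (config$cohort_mode == "closed" && n1 > 0 && n0 > 0)
    thresh <- lapply(config$q, function(qq) threshold_metrics(lp, y, qq))
  calib <- NULL
  if (config$cohort_mode == "closed" && n1 > 0 && n0 > 0)
    calib <- lapply(risk_5y_by_assumption, function(r5)
      tryCatch(calibration_table(r5, y), error = function(e) NULL))
  list(n = nrow(sub), n_events = n1, discrimination = disc, harrell = hc,
       threshold_metrics = thresh, calibration = calib)
}

#' Run the full external-validation study
#'
#' For each model: applies the cohort-definition exclusions (closed mode
#' additionally requires 5-year follow-up except for deaths), applies any
#' derivation rules, restricts to that model's complete cases, flags
#' applicability (age range blocks scoring; sex mismatch only flags),
#' scores the linear predictor and native-horizon absolute risk, converts
#' to 5-year risk under each configured hazard assumption, and evaluates
#' discrimination (AUC in the closed cohort, Harrell's C in the open
#' cohort), threshold metrics and decile calibration, stratified by sex.
#' Deterministic given the config; the report records provenance
#' (config hash, seed, exclusion flow counts).
#'
#' @param config A [run_config()].
#' @return An object of class `crc_validation_report`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "crc_run_config"))
  specs <- load_models(config$models)
  specs <- specs[sort(names(specs))]        # order-invariance
  cohort <- if (is.character(config$cohort)) read_cohort(config$cohort)
            else config$cohort

  cohort <- apply_exclusions(cohort, require_5y = config$cohort_mode == "closed")
  excl <- attr(cohort, "exclusion_counts")
  if (!is.null(config$derivation_rules))
    cohort <- derive_variables(cohort, config$derivation_rules)

  results <- lapply(specs, function(spec) {
    mask <- complete_case_mask(cohort, spec)
    app <- applicability(spec, cohort)
    age_ok <- attr(app, "age_ok")
    keep <- mask & age_ok                   # age rule blocks; sex only flags
    sub <- cohort[keep, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("model '", spec$model_id, "' has zero complete cases")
    lp <- linear_predictor(spec, sub)
    native <- absolute_risk(spec, sub, lp = lp)
    risk_5y <- lapply(config$assumptions, function(a) {
      pred <- data.frame(native_risk = native,
                         native_horizon_years = spec$native_horizon_years)
      convert_predictions(pred, a)$risk_5y
    })
    names(risk_5y) <- vapply(config$assumptions, assumption_label,
                             character(1))
    y <- outcome_at_5y(sub, config$outcome_scope)
    strata <- lapply(c(male = "male", female = "female"), function(sx) {
      i <- sub$sex == sx
      if (!any(i)) return(NULL)
      st <- evaluate_stratum(sub[i, , drop = FALSE], y[i], lp[i],
                             lapply(risk_5y, `[`, i), config)
      st$sex_applicable <- sx %in% spec$applicable_sexes
      st
    })
    list(model_id = spec$model_id, outcome = spec$outcome,
         form = spec$form,
         native_horizon_years = spec$native_horizon_years,
         n_complete = nrow(sub), strata = strata)
  })

  structure(list(
    models = results,
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      cohort_mode = config$cohort_mode,
                      outcome_scope = config$outcome_scope,
                      exclusion_counts = as.list(excl))),
    class = "crc_validation_report")
}

#' @export
print.crc_validation_report <- function(x, ...) {
  cat("<crc_validation_report> ", length(x$models), " model(s), ",
      x$provenance$cohort_mode, " cohort, outcome ",
      x$provenance$outcome_scope, "\n", sep = "")
  for (m in x$models) {
    cat("  ", m$model_id, " (", m$form, "): n = ", m$n_complete, sep = "")
    for (sx in names(m$strata)) {
      st <- m$strata[[sx]]
      if (is.null(st)) next
      val <- if (!is.null(st$discrimination))
        sprintf("AUC %.3f", st$discrimination$auc)
      else if (!is.null(st$harrell)) sprintf("C %.3f", st$harrell$c)
      else "-"
      cat("; ", sx, " ", val, sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Run the sensitivity-analysis battery
#'
#' Produces the base validation report plus one report per enabled
#' toggle: extreme-case imputation in both directions, term-set dropping
#' (models lacking every named term are flagged `not_applicable` rather
#' than erroring), surveillance exclusion, and the open-cohort design.
#' Each non-base report carries a per-model delta of discrimination
#' versus base.
#'
#' @param config A [run_config()] with toggles in `config$sensitivity`.
#' @return Named list of `crc_validation_report`s (always containing
#'   `base`), of class `crc_sensitivity_battery`.
#' @export
sensitivity_battery <- function(config) {
  stopifnot(inherits(config, "crc_run_config"))
  cohort <- if (is.character(config$cohort)) read_cohort(config$cohort)
            else config$cohort
  config$cohort <- cohort
  base <- run_validation(config)
  out <- list(base = base)
  tog <- config$sensitivity

  rerun <- function(cfg) run_validation(cfg)
  add_delta <- function(report) {
    report$delta_vs_base <- lapply(report$models, function(m) {
      b <- base$models[[m$model_id]]
      if (is.null(b)) return(NULL)
      sapply(c("male", "female"), function(sx) {
        a1 <- report$models[[m$model_id]]$strata[[sx]]
        a0 <- b$strata[[sx]]
        v1 <- if (!is.null(a1$discrimination)) a1$discrimination$auc
              else if (!is.null(a1$harrell)) a1$harrell$c else NA_real_
        v0 <- if (!is.null(a0$discrimination)) a0$discrimination$auc
              else if (!is.null(a0$harrell)) a0$harrell$c else NA_real_
        v1 - v0
      })
    })
    names(report$delta_vs_base) <- names(report$models)
    report
  }

  if (isTRUE(tog$extreme_impute_high)) {
    cfg <- config; cfg$cohort <- extreme_value_impute(cohort,
                                                      direction = "high")
    out$extreme_impute_high <- add_delta(rerun(cfg))
  }
  if (isTRUE(tog$extreme_impute_low)) {
    cfg <- config; cfg$cohort <- extreme_value_impute(cohort,
                                                      direction = "low")
    out$extreme_impute_low <- add_delta(rerun(cfg))
  }
  if (!is.null(tog$drop_term_sets)) {
    specs <- load_models(config$models)
    for (set_name in names(tog$drop_term_sets)) {
      drop <- tog$drop_term_sets[[set_name]]
      applicable <- vapply(specs, has_terms, logical(1), names = drop)
      if (!any(applicable)) {
        out[[paste0("drop_", set_name)]] <-
          structure(list(models = list(), not_applicable = TRUE,
                         provenance = base$provenance),
                    class = "crc_validation_report")
        next
      }
      reduced <- lapply(specs[applicable], function(s) {
        covs <- vapply(s$terms, function(t) t$covariate, character(1))
        drop_terms(s, intersect(drop, covs))
      })
      cfg <- config; cfg$models <- reduced
      out[[paste0("drop_", set_name)]] <- add_delta(rerun(cfg))
    }
  }
  if (isTRUE(tog$exclude_surveillance)) {
    cfg <- config; cfg$cohort <- exclude_surveillance(cohort)
    out$exclude_surveillance <- add_delta(rerun(cfg))
  }
  if (isTRUE(tog$open_cohort)) {
    cfg <- config; cfg$cohort_mode <- "open"
    out$open_cohort <- add_delta(rerun(cfg))
  }
  structure(out, class = "crc_sensitivity_battery")
}

round_half_even <- function(x, digits) round(x, digits)  # base round is IEC 60559

#' Write a validation report to disk
#'
#' Emits, per model and sex: a threshold-metric CSV with the standard row
#' set (Sensitivity, Specificity, LR+, LR-, PPV (%), NPV (%)) per
#' flagging fraction, a calibration CSV (group, n, mean predicted,
#' observed %) per hazard assumption, and a JSON summary holding the
#' unrounded values. Percentages are rounded half-even to 1 decimal place
#' and AUC / likelihood ratios to 2 in the CSVs; the JSON keeps full
#' precision.
#'
#' @param report A `crc_validation_report`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("csv", "json")`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, formats = c("csv", "json")) {
  stopifnot(inherits(report, "crc_validation_report"))
  if (length(report$models) == 0) stop("refusing to write an empty report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  if ("csv" %in% formats) {
    for (m in report$models) {
      for (sx in names(m$strata)) {
        st <- m$strata[[sx]]
        if (is.null(st) || is.null(st$threshold_metrics)) next
        tm <- st$threshold_metrics
        tab <- data.frame(metric = c("Sensitivity", "Specificity", "LR+",
                                     "LR-", "PPV (%)", "NPV (%)"))
        for (t in tm) {
          col <- c(round_half_even(t$sensitivity, 1),
                   round_half_even(t$specificity, 1),
                   round_half_even(t$lr_plus, 2),
                   round_half_even(t$lr_minus, 2),
                   round_half_even(t$ppv, 1),
                   round_half_even(t$npv, 1))
          tab[[sprintf("top_%d_pct", round(100 * t$q))]] <- col
        }
        f <- file.path(dir, paste0(m$model_id, "_", sx, "_thresholds.csv"))
        utils::write.csv(format(tab, trim = TRUE), f, row.names = FALSE,
                         quote = FALSE)
        paths <- c(paths, f)
        if (!is.null(st$calibration)) {
          for (an in names(st$calibration)) {
            cal <- st$calibration[[an]]
            if (is.null(cal)) next
            g <- cal$groups
            ctab <- data.frame(group = g$group, n = g$n,
                               mean_predicted = g$mean_predicted,
                               observed_pct = round_half_even(
                                 100 * g$observed_proportion, 1))
            f <- file.path(dir, paste0(m$model_id, "_", sx, "_calibration_",
                                       an, ".csv"))
            utils::write.csv(ctab, f, row.names = FALSE)
            paths <- c(paths, f)
          }
        }
      }
    }
  }

  if ("json" %in% formats) {
    summary <- list(provenance = report$provenance,
                    models = lapply(report$models, function(m) {
      list(model_id = m$model_id, n_complete = m$n_complete,
           strata = lapply(m$strata, function(st) {
             if (is.null(st)) return(NULL)
             out <- list(n = st$n, n_events = st$n_events,
                         sex_applicable = st$sex_applicable)
             if (!is.null(st$discrimination))
               out$auc <- unclass(st$discrimination)
             if (!is.null(st$harrell)) out$harrell_c <- st$harrell
             if (!is.null(st$calibration))
               out$hosmer_lemeshow <- lapply(st$calibration, function(cal)
                 if (!is.null(cal)) list(chi2 = cal$hl_chi2, df = cal$hl_df,
                                         p = cal$hl_p))
             out
           }))
    }))
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
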