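#' Define a covariate used by a risk model
#'
#' A covariate definition names one risk factor and fixes how a model is
#' allowed to refer to it: as a continuous quantity, a binary (present /
#' absent) indicator, or a categorical factor with a declared level set and
#' reference level.
#'
#' @param name Identifier; must match a column name in the harmonized cohort.
#' @param kind One of `"continuous"`, `"binary"`, `"categorical"`.
#' @param levels Ordered character vector of levels (categorical only).
#' @param unit Free-text unit, e.g. `"years"` or `"kg/m2"` (optional).
#' @param reference_level Reference level, must be one of `levels`
#'   (categorical only).
#' @return An object of class `crc_covariate`.
#' @export
covariate_def <- function(name, kind = c("continuous", "binary", "categorical"),
                          levels = NULL, unit = NULL, reference_level = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0)
      stop("categorical covariate '", name, "' needs a non-empty level set")
    if (is.null(reference_level) || !reference_level %in% levels)
      stop("categorical covariate '", name,
           "' needs a reference_level drawn from its levels")
  } else if (!is.null(levels)) {
    stop(kind, " covariate '", name, "' must not declare levels")
  }
  structure(
    list(name = as.character(name), kind = kind,
         levels = if (!is.null(levels)) as.character(levels),
         unit = unit, reference_level = reference_level),
    class = "crc_covariate"
  )
}

#' Define one additive term of a risk model
#'
#' A term attaches a coefficient (log-odds, log-hazard, log-relative-risk,
#' or integer points, depending on the model form) to a covariate, with an
#' optional transform chain applied to the covariate value before
#' multiplication.
#'
#' @param covariate Name of a declared covariate.
#' @param coefficient Numeric coefficient on the model's working scale.
#' @param level For categorical covariates, the level this term scores.
#' @param transform Transform chain, applied in list order. Each element is
#'   either the string `"identity"` or `"log"`, or a single-element named
#'   list: `list(center = offset)`, `list(scale = divisor)` or
#'   `list(indicator = value)`.
#' @return An object of class `crc_term`.
#' @export
term_spec <- function(covariate, coefficient, level = NULL, transform = list()) {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L)
  transform <- lapply(transform, identity)
  for (tr in transform) {
    ok <- (is.character(tr) && tr %in% c("identity", "log")) ||
      (is.list(tr) && length(tr) == 1L &&
         names(tr) %in% c("center", "scale", "indicator"))
    if (!ok) stop("malformed transform element for term on '", covariate, "'")
  }
  structure(
    list(covariate = as.character(covariate), level = level,
         coefficient = as.numeric(coefficient), transform = transform),
    class = "crc_term"
  )
}

#' Declarative specification of a published risk model
#'
#' Represents one published incident colorectal-cancer risk model in a form
#' the scoring engine can evaluate. Four functional families are supported:
#'
#' * `logistic` — risk = inverse-logit(intercept + linear predictor);
#' * `cox` — risk = 1 - S0^exp(lp - mean linear predictor), with `S0` the
#'   baseline survival at the model's native horizon;
#' * `points` — an integer point sum mapped to absolute risk through a
#'   non-decreasing step function;
#' * `rr_product` — a product of per-term relative risks scaling a
#'   configurable baseline absolute risk, capped at 1.
#'
#' @param model_id Identifier for the model.
#' @param outcome `"CRC"` (colorectal) or `"colon"`.
#' @param form One of `"logistic"`, `"cox"`, `"points"`, `"rr_product"`.
#' @param native_horizon_years Horizon (in years) over which the model's
#'   absolute risk is expressed, typically 5, 10 or 20.
#' @param covariates List of [covariate_def()] objects.
#' @param terms List of [term_spec()] objects.
#' @param intercept Intercept on the log-odds scale (logistic form).
#' @param baseline_survival Baseline survival S0 at the native horizon,
#'   in (0, 1] (cox form).
#' @param mean_linear_predictor Centering constant for the cox form.
#' @param baseline_risk Baseline absolute risk in \[0, 1) at the native
#'   horizon (rr_product form).
#' @param points_to_risk Data frame with columns `points` (integer
#'   thresholds, strictly increasing) and `risk` (non-decreasing
#'   probabilities); a point total maps to the risk of the largest
#'   threshold it reaches (points form).
#' @param applicable_sexes Subset of `c("male", "female")` the model was
#'   developed for. Advisory: records of other sexes are scored but
#'   flagged, not dropped.
#' @param applicable_age_range Optional length-2 numeric, closed age
#'   interval outside which risk is not calculated.
#' @return An object of class `crc_model_spec` (validated).
#' @seealso [validate_model_spec()], [linear_predictor()], [absolute_risk()]
#' @examples
#' spec <- model_spec(
#'   model_id = "toy", form = "logistic", native_horizon_years = 5,
#'   intercept = -6,
#'   covariates = list(covariate_def("age", "continuous", unit = "years")),
#'   terms = list(term_spec("age", 0.08, transform = list(list(center = 40))))
#' )
#' absolute_risk(spec, data.frame(age = 60))
#' @export
model_spec <- function(model_id,
                       outcome = c("CRC", "colon"),
                       form = c("logistic", "cox", "points", "rr_product"),
                       native_horizon_years,
                       covariates = list(), terms = list(),
                       intercept = NULL, baseline_survival = NULL,
                       mean_linear_predictor = NULL, baseline_risk = NULL,
                       points_to_risk = NULL,
                       applicable_sexes = c("male", "female"),
                       applicable_age_range = NULL) {
  outcome <- match.arg(outcome)
  form <- match.arg(form)
  spec <- structure(
    list(model_id = as.character(model_id), outcome = outcome, form = form,
         native_horizon_years = as.numeric(native_horizon_years),
         covariates = covariates, terms = terms,
         intercept = intercept, baseline_survival = baseline_survival,
         mean_linear_predictor = mean_linear_predictor,
         baseline_risk = baseline_risk, points_to_risk = points_to_risk,
         applicable_sexes = as.character(applicable_sexes),
         applicable_age_range = applicable_age_range),
    class = "crc_model_spec"
  )
  validate_model_spec(spec)
}

#' Validate a model specification
#'
#' Checks every structural invariant of a [model_spec()]: that exactly the
#' baseline fields demanded by the form are present, that every term
#' resolves to a declared covariate with level usage matching the covariate
#' kind, that a points-to-risk map is non-decreasing with integer point
#' coefficients, and that the age range (if any) is a proper interval.
#'
#' @param spec A `crc_model_spec`.
#' @return The spec, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_model_spec <- function(spec) {
  stopifnot(inherits(spec, "crc_model_spec"))
  if (!is.numeric(spec$native_horizon_years) || spec$native_horizon_years <= 0)
    stop("native_horizon_years must be a positive number")

  needed <- switch(spec$form,
    logistic   = "intercept",
    cox        = c("baseline_survival", "mean_linear_predictor"),
    points     = "points_to_risk",
    rr_product = "baseline_risk")
  all_baseline <- c("intercept", "baseline_survival", "mean_linear_predictor",
                    "baseline_risk", "points_to_risk")
  for (f in needed)
    if (is.null(spec[[f]]))
      stop("form '", spec$form, "' requires field '", f, "'")
  extra <- setdiff(all_baseline, needed)
  present_extra <- extra[!vapply(spec[extra], is.null, logical(1))]
  if (length(present_extra))
    stop("form '", spec$form, "' must not carry field(s): ",
         paste(present_extra, collapse = ", "))

  if (spec$form == "cox") {
    if (spec$baseline_survival <= 0 || spec$baseline_survival > 1)
      stop("baseline_survival must lie in (0, 1]")
  }
  if (spec$form == "rr_product") {
    if (spec$baseline_risk < 0 || spec$baseline_risk >= 1)
      stop("baseline_risk must lie in [0, 1)")
  }
  if (spec$form == "points") {
    m <- spec$points_to_risk
    if (!is.data.frame(m) || !all(c("points", "risk") %in% names(m)) ||
        nrow(m) == 0)
      stop("points_to_risk must be a data frame with columns points, risk")
    if (is.unsorted(m$points, strictly = TRUE))
      stop("points_to_risk thresholds must be strictly increasing")
    if (is.unsorted(m$risk))                       # pairwise non-decreasing
      stop("points_to_risk map must be non-decreasing in risk")
    if (any(m$risk < 0 | m$risk > 1))
      stop("points_to_risk risks must be probabilities")
  }

  cov_names <- vapply(spec$covariates, function(cv) cv$name, character(1))
  if (anyDuplicated(cov_names))
    stop("duplicate covariate names in spec")
  for (tm in spec$terms) {
    i <- match(tm$covariate, cov_names)
    if (is.na(i))
      stop("term refers to unknown covariate '", tm$covariate, "'")
    cv <- spec$covariates[[i]]
    if (cv$kind == "categorical") {
      if (is.null(tm$level))
        stop("term on categorical covariate '", cv$name, "' needs a level")
      if (!tm$level %in% cv$levels)
        stop("term level '", tm$level, "' not among levels of '", cv$name, "'")
    } else if (!is.null(tm$level)) {
      stop("term on ", cv$kind, " covariate '", cv$name,
           "' must not carry a level")
    }
    if (spec$form == "points" && tm$coefficient != round(tm$coefficient))
      stop("points-form coefficients must be integers ('", cv$name, "')")
  }

  if (!all(spec$applicable_sexes %in% c("male", "female")) ||
      length(spec$applicable_sexes) == 0)
    stop("applicable_sexes must be a non-empty subset of male/female")
  r <- spec$applicable_age_range
  if (!is.null(r)) {
    if (length(r) != 2L || !is.numeric(r) || r[1] >= r[2])
      stop("applicable_age_range must be a numeric interval with lower < upper")
  }
  invisible(spec)
}

#' @export
print.crc_model_spec <- function(x, ...) {
  cat("<crc_model_spec> ", x$model_id, "\n", sep = "")
  cat("  form: ", x$form, "   outcome: ", x$outcome,
      "   native horizon: ", x$native_horizon_years, "y\n", sep = "")
  cat("  terms: ", length(x$terms), " over ",
      length(unique(vapply(x$terms, function(t) t$covariate, character(1)))),
      " covariate(s)\n", sep = "")
  cat("  applicable sexes: ", paste(x$applicable_sexes, collapse = ", "),
      if (!is.null(x$applicable_age_range))
        paste0("   ages [", x$applicable_age_range[1], ", ",
               x$applicable_age_range[2], "]"),
      "\n", sep = "")
  invisible(x)
}

# Evaluate one term's transformed covariate values over a cohort.
# Missing covariate values propagate to NA.
term_values <- function(term, cov, cohort) {
  if (!cov$name %in% names(cohort))
    stop("covariate '", cov$name, "' missing from cohort")
  x <- cohort[[cov$name]]
  v <- switch(cov$kind,
    categorical = as.numeric(as.character(x) == term$level),
    binary      = as.numeric(as.logical(x)),
    continuous  = as.numeric(x))
  for (tr in term$transform) {
    if (is.character(tr)) {
      v <- switch(tr, identity = v, log = log(v))
    } else {
      nm <- names(tr)
      v <- switch(nm,
        center    = v - tr[[1]],
        scale     = v / tr[[1]],
        indicator = as.numeric(v == tr[[1]]))
    }
  }
  v
}

#' Linear predictor (or point total) of a model over a cohort
#'
#' Sums coefficient times transformed covariate value over all terms. For
#' the points form this is the integer point total. Records missing any
#' required covariate get `NA` (complete-case handling is the caller's
#' responsibility; see [complete_case_mask()]).
#'
#' @param spec A validated `crc_model_spec`.
#' @param cohort Data frame of harmonized participant records.
#' @return Numeric vector, one value per row of `cohort`.
#' @export
linear_predictor <- function(spec, cohort) {
  n <- nrow(cohort)
  lp <- numeric(n)
  cov_names <- vapply(spec$covariates, function(cv) cv$name, character(1))
  for (tm in spec$terms) {
    cv <- spec$covariates[[match(tm$covariate, cov_names)]]
    lp <- lp + tm$coefficient * term_values(tm, cv, cohort)
  }
  lp
}

#' Absolute risk at the model's native horizon
#'
#' Maps the linear predictor to an absolute risk according to the model
#' form (see [model_spec()] for the four families). Rows with missing
#' covariates yield `NA`.
#'
#' @inheritParams linear_predictor
#' @param lp Optional precomputed linear predictor (saves recomputation).
#' @return Numeric vector of probabilities at the native horizon.
#' @export
absolute_risk <- function(spec, cohort, lp = NULL) {
  if (is.null(lp)) lp <- linear_predictor(spec, cohort)
  switch(spec$form,
    logistic = stats::plogis(spec$intercept + lp),
    cox = 1 - spec$baseline_survival ^ exp(lp - spec$mean_linear_predictor),
    rr_product = pmin(1, spec$baseline_risk * exp(lp)),
    points = {
      m <- spec$points_to_risk
      idx <- findInterval(lp, m$points)
      out <- rep(NA_real_, length(lp))
      ok <- !is.na(idx)
      out[ok & idx >= 1] <- m$risk[idx[ok & idx >= 1]]
      # totals below the lowest threshold take the lowest mapped risk
      out[ok & idx == 0] <- m$risk[1]
      out
    })
}

#' Applicability of a model to each participant
#'
#' A record is applicable when its sex belongs to the model's
#' `applicable_sexes` and its age falls inside `applicable_age_range`
#' (vacuously true when no range is declared). Sex applicability is
#' advisory: the validation pipeline scores male-derived models on women
#' and reports the flag rather than filtering, while the age rule (used by
#' models whose published software refuses ages outside 50-89) is treated
#' as blocking by the pipeline.
#'
#' @inheritParams linear_predictor
#' @return Logical vector, with attributes `sex_ok` and `age_ok` carrying
#'   the two component flags.
#' @export
applicability <- function(spec, cohort) {
  sex_ok <- as.character(cohort$sex) %in% spec$applicable_sexes
  if (!is.null(spec$applicable_age_range)) {
    r <- spec$applicable_age_range
    age_ok <- cohort$age >= r[1] & cohort$age <= r[2]
  } else {
    age_ok <- rep(TRUE, nrow(cohort))
  }
  structure(sex_ok & age_ok, sex_ok = sex_ok, age_ok = age_ok)
}

#' Drop named terms from a model specification
#'
#' Removes every term whose covariate name is in `names`, leaving all
#' other fields untouched. Used by the sensitivity analyses that re-score
#' models without aspirin/NSAID/hormonal or deprivation terms.
#'
#' @param spec A validated `crc_model_spec`.
#' @param names Character vector of covariate names whose terms to drop.
#' @return A new validated `crc_model_spec`.
#' @export
drop_terms <- function(spec, names) {
  if (length(names) == 0) return(spec)
  term_covs <- vapply(spec$terms, function(t) t$covariate, character(1))
  unknown <- setdiff(names, term_covs)
  if (length(unknown))
    stop("no term(s) named: ", paste(unknown, collapse = ", "))
  spec$terms <- spec$terms[!term_covs %in% names]
  validate_model_spec(spec)
  spec
}

#' Does a spec contain any term on the named covariates?
#' @inheritParams drop_terms
#' @return Logical scalar.
#' @export
has_terms <- function(spec, names) {
  any(vapply(spec$terms, function(t) t$covariate, character(1)) %in% names)
}

# ---- serialization ----------------------------------------------------------

spec_to_list <- function(spec) {
  l <- list(
    schema_version = 1L,
    model_id = spec$model_id, outcome = spec$outcome, form = spec$form,
    native_horizon_years = spec$native_horizon_years,
    covariates = lapply(spec$covariates, function(cv)
      Filter(Negate(is.null), unclass(cv))),
    terms = lapply(spec$terms, function(tm) {
      out <- Filter(Negate(is.null), unclass(tm))
      if (length(out$transform) == 0) out$transform <- NULL
      out
    }),
    applicable_sexes = spec$applicable_sexes)
  for (f in c("intercept", "baseline_survival", "mean_linear_predictor",
              "baseline_risk"))
    if (!is.null(spec[[f]])) l[[f]] <- spec[[f]]
  if (!is.null(spec$points_to_risk))
    l$points_to_risk <- list(points = spec$points_to_risk$points,
                             risk = spec$points_to_risk$risk)
  if (!is.null(spec$applicable_age_range))
    l$applicable_age_range <- as.numeric(spec$applicable_age_range)
  l
}

list_to_spec <- function(l) {
  covs <- lapply(l$covariates, function(cv)
    covariate_def(cv$name, cv$kind, levels = cv$levels, unit = cv$unit,
                  reference_level = cv$reference_level))
  terms <- lapply(l$terms, function(tm) {
    tr <- tm$transform
    if (is.null(tr)) tr <- list()
    # yaml/json read named single pairs back as lists already; strings stay
    tr <- lapply(tr, function(el) if (is.list(el) || is.character(el)) el
                 else stop("malformed transform"))
    term_spec(tm$covariate, tm$coefficient, level = tm$level, transform = tr)
  })
  p2r <- NULL
  if (!is.null(l$points_to_risk))
    p2r <- data.frame(points = as.numeric(l$points_to_risk$points),
                      risk = as.numeric(l$points_to_risk$risk))
  model_spec(
    model_id = l$model_id, outcome = l$outcome, form = l$form,
    native_horizon_years = l$native_horizon_years,
    covariates = covs, terms = terms,
    intercept = l$intercept, baseline_survival = l$baseline_survival,
    mean_linear_predictor = l$mean_linear_predictor,
    baseline_risk = l$baseline_risk, points_to_risk = p2r,
    applicable_sexes = l$applicable_sexes,
    applicable_age_range = if (!is.null(l$applicable_age_range))
      as.numeric(l$applicable_age_range))
}

#' Read / write model specification files
#'
#' One model per file, JSON or YAML (chosen by extension: `.json`,
#' `.yaml`, `.yml`). Field names match the `crc_model_spec` slots; the
#' round trip spec -> file -> spec is the identity on all fields.
#'
#' @param path File path.
#' @return `read_model_spec` returns a validated `crc_model_spec`.
#' @export
read_model_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  l <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported spec extension: ", ext))
  # jsonlite leaves scalars as length-1 lists when simplifyVector = FALSE
  l <- rapply(l, function(x) x, how = "replace")
  unbox1 <- function(x) if (is.list(x) && length(x) == 1L &&
                            is.null(names(x)) && !is.list(x[[1]])) x[[1]] else x
  l$applicable_sexes <- unlist(l$applicable_sexes)
  if (!is.null(l$applicable_age_range))
    l$applicable_age_range <- unlist(l$applicable_age_range)
  for (f in c("model_id", "outcome", "form", "native_horizon_years",
              "intercept", "baseline_survival", "mean_linear_predictor",
              "baseline_risk"))
    l[[f]] <- unbox1(l[[f]])
  l$covariates <- lapply(l$covariates, function(cv) {
    cv <- lapply(cv, unbox1)
    cv$levels <- if (!is.null(cv$levels)) unlist(cv$levels)
    cv
  })
  l$terms <- lapply(l$terms, function(tm) {
    tm[setdiff(names(tm), "transform")] <-
      lapply(tm[setdiff(names(tm), "transform")], unbox1)
    if (!is.null(tm$transform))
      tm$transform <- lapply(tm$transform, function(el) {
        el <- unbox1(el)
        if (is.list(el)) lapply(el, unbox1) else el
      })
    tm
  })
  if (!is.null(l$points_to_risk))
    l$points_to_risk <- lapply(l$points_to_risk, unlist)
  list_to_spec(l)
}

#' @rdname read_model_spec
#' @param spec A validated `crc_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  validate_model_spec(spec)
  l <- spec_to_list(spec)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                                null = "null"),
    yaml = ,
    yml  = yaml::write_yaml(l, path, precision = 17),
    stop("unsupported spec extension: ", ext))
  invisible(path)
}
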