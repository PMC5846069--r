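#' Hazard assumption for risk-horizon conversion
#'
#' Converting an absolute risk stated over one period to another requires
#' an assumption about how hazard accrues over time. Two shapes are
#' supported, bracketing the plausible range for incident colorectal
#' cancer:
#'
#' * `constant` — hazard accrues uniformly, so cumulative hazard scales
#'   linearly with time (matches a cohort in which the incident rate is
#'   observed to be constant over follow-up);
#' * `doubling` — risk doubles every `doubling_period_years`, interpreted
#'   on the cumulative-hazard scale: the hazard accrued in successive
#'   blocks of one period forms a geometric series with ratio 2
#'   (reflecting incidence rates that rise steeply with age).
#'
#' @param shape `"constant"` or `"doubling"`.
#' @param doubling_period_years Doubling period in years (doubling shape
#'   only; default 5).
#' @return An object of class `crc_hazard_assumption`.
#' @export
hazard_assumption <- function(shape = c("constant", "doubling"),
                              doubling_period_years = 5) {
  shape <- match.arg(shape)
  if (shape == "doubling" && doubling_period_years <= 0)
    stop("doubling_period_years must be positive")
  structure(list(shape = shape,
                 doubling_period_years = if (shape == "doubling")
                   doubling_period_years),
            class = "crc_hazard_assumption")
}

#' Convert an absolute risk between horizons
#'
#' Works on the cumulative-hazard scale `H = -log(1 - p)`. Under the
#' constant shape, `H_target = H_native * target / native`. Under the
#' doubling shape with period `d`, cumulative hazard grows like
#' `2^(t/d) - 1` (continuous compounding of the geometric block series),
#' so `H_target = H_native * (2^(target/d) - 1) / (2^(native/d) - 1)`;
#' for a native horizon of `k` periods converted down to one period this
#' reduces to division by `2^k - 1` (e.g. 1/3 for 10 to 5 years, 1/15
#' for 20 to 5 years with a 5-year doubling period).
#'
#' A linear alternative (`method = "linear"`), which scales the
#' probability itself by the same ratio and caps at 1, is provided
#' because published validations do not always state which arithmetic
#' they used; the two agree to first order at typical 5-year colorectal
#' cancer risks (~0.5%).
#'
#' @param p Probability vector, each in `[0, 1)`.
#' @param native_horizon Horizon (years) over which `p` is expressed.
#' @param target_horizon Horizon to convert to.
#' @param assumption A [hazard_assumption()].
#' @param method `"hazard"` (default) or `"linear"`.
#' @return Probability vector on the target horizon.
#' @export
convert_risk <- function(p, native_horizon, target_horizon,
                         assumption = hazard_assumption("constant"),
                         method = c("hazard", "linear")) {
  method <- match.arg(method)
  if (native_horizon <= 0 || target_horizon <= 0)
    stop("horizons must be positive")
  bad <- !is.na(p) & (p < 0 | p >= 1)
  if (any(bad))
    stop("p must lie in [0, 1); a risk of 1 has infinite cumulative hazard")
  ratio <- switch(assumption$shape,
    constant = target_horizon / native_horizon,
    doubling = {
      d <- assumption$doubling_period_years
      (2 ^ (target_horizon / d) - 1) / (2 ^ (native_horizon / d) - 1)
    })
  if (method == "linear") return(pmin(1, p * ratio))
  1 - exp(log1p(-p) * ratio)          # 1 - (1-p)^ratio on the hazard scale
}

#' Fill 5-year risks in a batch of predictions
#'
#' Sets the `risk_5y` column of a prediction table from `native_risk` and
#' the per-row native horizon. Models already expressed over 5 years pass
#' through unchanged unless `force_all` is set, which re-derives even
#' native-5-year risks through the assumption for cross-model
#' comparability.
#'
#' @param predictions Data frame with columns `native_risk` and
#'   `native_horizon_years`.
#' @param assumption A [hazard_assumption()].
#' @param target_horizon Target horizon, default 5 years.
#' @param force_all Convert native-target-horizon rows too?
#' @param method Passed to [convert_risk()].
#' @return `predictions` with `risk_5y` filled (`NA` where `native_risk`
#'   is missing).
#' @export
convert_predictions <- function(predictions,
                                assumption = hazard_assumption("constant"),
                                target_horizon = 5, force_all = FALSE,
                                method = "hazard") {
  stopifnot(all(c("native_risk", "native_horizon_years") %in%
                  names(predictions)))
  out <- rep(NA_real_, nrow(predictions))
  for (h in unique(predictions$native_horizon_years)) {
    idx <- which(predictions$native_horizon_years == h)
    p <- predictions$native_risk[idx]
    out[idx] <- if (h == target_horizon && !force_all) p
      else convert_risk(p, h, target_horizon, assumption, method)
  }
  predictions$risk_5y <- out
  predictions
}
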