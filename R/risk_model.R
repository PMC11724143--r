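#' Parameters of the log-linear blood-pressure risk model
#'
#' The model relates a sustained reduction in clinic systolic blood pressure
#' (delta SBP, mmHg) to the relative risk of the primary cardiovascular
#' endpoint through \code{RR = exp(alpha * delta)}, where
#' \code{alpha = log(1 - rrr_per_5mmhg) / 5} is the per-mmHg log relative
#' risk. The default calibration, a 10% relative risk reduction per 5 mmHg,
#' follows the BPLTTC individual-patient meta-analysis of blood-pressure
#' lowering trials.
#'
#' @param rrr_per_5mmhg relative risk reduction for a 5 mmHg reduction in
#'   systolic blood pressure, as a fraction in (0, 1). Default 0.10.
#' @return an object of class \code{"risk_model_params"} with fields
#'   \code{rrr_per_5mmhg} and \code{alpha}.
#' @examples
#' p <- risk_model_params()
#' rr_from_delta(5, p)   # 0.90
#' @export
risk_model_params <- function(rrr_per_5mmhg = 0.10) {
  if (!is.numeric(rrr_per_5mmhg) || length(rrr_per_5mmhg) != 1 ||
      rrr_per_5mmhg <= 0 || rrr_per_5mmhg >= 1) {
    stop("rrr_per_5mmhg must be a single number strictly between 0 and 1")
  }
  structure(list(rrr_per_5mmhg = rrr_per_5mmhg,
                 alpha = log(1 - rrr_per_5mmhg) / 5),
            class = "risk_model_params")
}

#' @export
print.risk_model_params <- function(x, ...) {
  cat(sprintf("Log-linear BP risk model: RRR %.1f%% per 5 mmHg (alpha = %.5f per mmHg)\n",
              100 * x$rrr_per_5mmhg, x$alpha))
  invisible(x)
}

#' Relative risk implied by a systolic blood-pressure reduction
#'
#' @param delta_sbp reduction in systolic blood pressure, mmHg (>= 0;
#'   vectorized).
#' @param params a [risk_model_params()] object.
#' @return relative risk in (0, 1]; 1 when \code{delta_sbp} is 0.
#' @export
rr_from_delta <- function(delta_sbp, params = risk_model_params()) {
  stopifnot(inherits(params, "risk_model_params"))
  if (any(delta_sbp < 0)) {
    stop("delta_sbp must be non-negative (truncation of draws happens upstream)")
  }
  exp(params$alpha * delta_sbp)
}

#' Convert a cumulative event risk to a constant yearly hazard
#'
#' Inverse of [risk_from_hazard()]: \code{h = -log(1 - r) / horizon}.
#'
#' @param r cumulative event probability over the horizon, in \[0, 1).
#' @param horizon_years horizon length in years (> 0).
#' @export
hazard_from_risk <- function(r, horizon_years = 10) {
  if (any(r < 0) || any(r >= 1)) stop("r must lie in [0, 1)")
  if (horizon_years <= 0) stop("horizon_years must be positive")
  -log(1 - r) / horizon_years
}

#' Convert a constant yearly hazard to a cumulative event risk
#'
#' \code{r = 1 - exp(-h * horizon)}.
#'
#' @param h constant hazard per year (>= 0).
#' @param horizon_years horizon length in years (> 0).
#' @export
risk_from_hazard <- function(h, horizon_years = 10) {
  if (any(h < 0)) stop("h must be non-negative")
  if (horizon_years <= 0) stop("horizon_years must be positive")
  1 - exp(-h * horizon_years)
}

#' Back-transform observed risk to untreated (baseline) risk
#'
#' Removes the effect of blood-pressure-lowering treatment present at
#' baseline from an observed cumulative risk. The relative risk implied by
#' the baseline delta SBP is applied on the cumulative-hazard scale
#' (proportional hazards): \code{H0 = H_obs / RR(delta)}, which keeps the
#' untreated risk strictly below 1 and makes the transformation exactly
#' invertible by the forward treatment-effect application.
#'
#' @param r_obs observed cumulative risk over the horizon, in (0, 1);
#'   vectorized.
#' @param baseline_delta_sbp systolic blood-pressure reduction (mmHg)
#'   attributable to treatment present at baseline; 0 for untreated patients.
#' @param params a [risk_model_params()] object.
#' @param horizon_years horizon over which \code{r_obs} is measured.
#' @return a data.frame with columns \code{r0} (untreated cumulative risk),
#'   \code{h0} (untreated constant hazard per year) and \code{flagged}
#'   (TRUE where the back-transformed risk is numerically indistinguishable
#'   from 1 and the patient should be excluded as implausible).
#' @export
untreated_risk_from_observed <- function(r_obs, baseline_delta_sbp,
                                         params = risk_model_params(),
                                         horizon_years = 10) {
  if (any(r_obs <= 0) || any(r_obs >= 1)) stop("r_obs must lie strictly in (0, 1)")
  H_obs <- -log(1 - r_obs)
  H0 <- H_obs / rr_from_delta(baseline_delta_sbp, params)
  r0 <- 1 - exp(-H0)
  data.frame(r0 = r0,
             h0 = H0 / horizon_years,
             flagged = r0 >= 1 - 1e-12)
}
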