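#' Association rate constant from a concentration series
#'
#' Fits the observed fast phase against partner concentration by linear
#' regression, weighted by 1/SE^2 when rate SEs are supplied. The slope is
#' the fast association rate constant k_ass,fast and the intercept the
#' apparent off-rate contribution.
#'
#' @param partner_conc partner concentrations (M), >= 4 values.
#' @param lambda_fast observed fast rates (s^-1).
#' @param lambda_se optional standard errors of the fast rates.
#' @return list with `k_ass_fast`, `k_ass_fast_se` (M^-1 s^-1),
#'   `intercept`, `intercept_se` (s^-1) and the `lm` fit in `$fit`.
#' @export
fit_association_series <- function(partner_conc, lambda_fast,
                                   lambda_se = NULL) {
  ok <- is.finite(partner_conc) & is.finite(lambda_fast)
  if (!is.null(lambda_se)) ok <- ok & is.finite(lambda_se)
  partner_conc <- partner_conc[ok]; lambda_fast <- lambda_fast[ok]
  if (!is.null(lambda_se)) lambda_se <- lambda_se[ok]
  if (length(partner_conc) < 4L)
    stop("at least 4 concentrations with fast-rate estimates required",
         call. = FALSE)
  w <- if (!is.null(lambda_se) && all(lambda_se > 0)) 1 / lambda_se^2
  fit <- stats::lm(lambda_fast ~ partner_conc, weights = w)
  # noiseless series fit exactly; the perfect-fit warning is expected
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- co["partner_conc", "Estimate"]
  if (slope <= 0)
    stop("fitted association slope is not positive (unphysical)",
         call. = FALSE)
  list(k_ass_fast = slope,
       k_ass_fast_se = co["partner_conc", "Std. Error"],
       intercept = co["(Intercept)", "Estimate"],
       intercept_se = co["(Intercept)", "Std. Error"],
       fit = fit)
}

#' Summarize the concentration-independent slow association phase
#'
#' Reports the mean and standard error of the observed slow rates together
#' with the p-value of a regression slope against concentration, so the
#' claimed concentration independence can be checked.
#'
#' @param partner_conc partner concentrations (M), >= 4 values.
#' @param lambda_slow observed slow rates (s^-1).
#' @return list with `k_ass_slow`, `k_ass_slow_se`, `slope_p`.
#' @export
summarize_slow_phase <- function(partner_conc, lambda_slow) {
  ok <- is.finite(partner_conc) & is.finite(lambda_slow)
  partner_conc <- partner_conc[ok]; lambda_slow <- lambda_slow[ok]
  if (length(partner_conc) < 4L)
    stop("at least 4 slow-rate estimates required", call. = FALSE)
  fit <- stats::lm(lambda_slow ~ partner_conc)
  co <- suppressWarnings(summary(fit)$coefficients)
  list(k_ass_slow = mean(lambda_slow),
       k_ass_slow_se = stats::sd(lambda_slow) / sqrt(length(lambda_slow)),
       slope_p = co["partner_conc", "Pr(>|t|)"])
}

#' Dissociation rate constant from a competition series
#'
#' Fits observed displacement rates against competitor concentration with
#' a saturating hyperbola through the origin,
#' `k_obs(c) = k_diss * c / (c + K_half)`, and reports the asymptote
#' k_diss with its standard error. Warns when the series has not visibly
#' plateaued; errors when k_obs decreases with concentration
#' (model mismatch).
#'
#' @param competitor_conc competitor concentrations (M), >= 4 distinct.
#' @param k_obs observed apparent dissociation rates (s^-1), > 0.
#' @param k_obs_se optional standard errors (used as 1/SE^2 weights).
#' @return list with `k_diss`, `k_diss_se` (s^-1), `k_half`, `k_half_se`
#'   (M), `converged`, `saturated` (K_half unidentifiable).
#' @export
fit_dissociation_asymptote <- function(competitor_conc, k_obs,
                                       k_obs_se = NULL) {
  ok <- is.finite(competitor_conc) & is.finite(k_obs)
  competitor_conc <- competitor_conc[ok]; k_obs <- k_obs[ok]
  if (!is.null(k_obs_se)) k_obs_se <- k_obs_se[ok]
  if (length(unique(competitor_conc)) < 4L)
    stop("at least 4 distinct competitor concentrations required",
         call. = FALSE)
  if (any(k_obs <= 0)) stop("'k_obs' must be positive", call. = FALSE)

  lf <- stats::lm(k_obs ~ competitor_conc)
  slo <- suppressWarnings(summary(lf)$coefficients["competitor_conc", ])
  if (slo["Estimate"] < 0 && slo["Pr(>|t|)"] < 0.05)
    stop("k_obs decreases with competitor concentration: ",
         "saturating-hyperbola model mismatch", call. = FALSE)

  ks <- sort(k_obs, decreasing = TRUE)
  if (length(ks) >= 2L && (ks[1] - ks[2]) / ks[1] > 0.1)
    warning("competition series may not have plateaued: ",
            "max k_obs exceeds second max by > 10%", call. = FALSE)

  # saturated limit: constant k_obs, K_half unidentifiable
  if (stats::sd(k_obs) / mean(k_obs) < 1e-3) {
    return(list(k_diss = mean(k_obs),
                k_diss_se = stats::sd(k_obs) / sqrt(length(k_obs)),
                k_half = NA_real_, k_half_se = NA_real_,
                converged = TRUE, saturated = TRUE))
  }

  kd0 <- max(k_obs) * 1.05
  kh0 <- competitor_conc[which.min(abs(k_obs - kd0 / 2))]
  if (kh0 <= 0) kh0 <- stats::median(competitor_conc)
  # nlsLM rejects an explicit NULL weights argument, so fall back to
  # unit weights when no usable SEs are supplied
  w <- if (!is.null(k_obs_se) && all(is.finite(k_obs_se)) &&
           all(k_obs_se > 0)) 1 / k_obs_se^2 else rep(1, length(k_obs))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      k_obs ~ kd * competitor_conc / (competitor_conc + exp(lkh)),
      start = list(kd = kd0, lkh = log(kh0)), weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(k_diss = NA_real_, k_diss_se = NA_real_, k_half = NA_real_,
                k_half_se = NA_real_, converged = FALSE, saturated = FALSE))
  }
  co <- summary(fit)$coefficients
  list(k_diss = co["kd", "Estimate"],
       k_diss_se = co["kd", "Std. Error"],
       k_half = exp(co["lkh", "Estimate"]),
       k_half_se = exp(co["lkh", "Estimate"]) * co["lkh", "Std. Error"],
       converged = TRUE, saturated = FALSE)
}
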