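#' Depletion-corrected bound fraction
#'
#' Exact mass-action solution for one-site binding at finite probe
#' concentration: the physical root of
#' `[PL]^2 - (P + L + Kd)[PL] + P L = 0`, returned as `[PL]/P`. Computed in
#' the numerically stable form `2 P L / (S + sqrt(S^2 - 4 P L))` with
#' `S = P + L + Kd`.
#'
#' @param partner_total total partner concentration(s) L (M); vectorized.
#' @param probe_total total labelled-probe concentration P (M).
#' @param kd dissociation constant (M), > 0.
#' @return bound fraction(s) in \[0, 1\].
#' @export
fraction_bound <- function(partner_total, probe_total, kd) {
  if (any(partner_total < 0) || probe_total < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  if (kd <= 0) stop("'kd' must be > 0", call. = FALSE)
  if (probe_total == 0) return(rep(0, length(partner_total)))
  S <- probe_total + partner_total + kd
  pl <- 2 * probe_total * partner_total /
    (S + sqrt(S^2 - 4 * probe_total * partner_total))
  pmin(pmax(pl / probe_total, 0), 1)
}

#' Fit an anisotropy titration isotherm
#'
#' Nonlinear least-squares fit of
#' `r(L) = r_free + (r_bound - r_free) * fraction_bound(L, P, Kd)` with Kd
#' on the log scale. Anisotropy averaging is used directly (total
#' fluorescence intensity assumed unchanged on binding). A
#' `poorly_determined` flag is raised when the fitted Kd exceeds the
#' largest titrated concentration or its relative SE exceeds 50%, the
#' situation low-affinity variants produce.
#'
#' @param partner_total titrated partner concentrations (M), >= 6 points.
#' @param anisotropy measured anisotropies (unitless, within \[0, 0.4\]).
#' @param probe_conc fixed labelled-probe concentration (M).
#' @return object of class `equilibrium_result`: list with `kd_equb`,
#'   `kd_se` (M), `r_free`, `r_bound`, `converged`, `poorly_determined`.
#' @export
fit_anisotropy_isotherm <- function(partner_total, anisotropy, probe_conc) {
  ok <- is.finite(partner_total) & is.finite(anisotropy)
  partner_total <- partner_total[ok]; anisotropy <- anisotropy[ok]
  if (length(partner_total) < 6L)
    stop("at least 6 titration points required", call. = FALSE)
  if (any(anisotropy < -0.05) || any(anisotropy > 0.45))
    warning("anisotropy outside the physically plausible range [0, 0.4]",
            call. = FALSE)
  ord <- order(partner_total)
  partner_total <- partner_total[ord]; anisotropy <- anisotropy[ord]

  rf0 <- min(anisotropy); rb0 <- max(anisotropy)
  half <- rf0 + 0.5 * (rb0 - rf0)
  above <- which(anisotropy >= half & partner_total > 0)
  kd0 <- if (length(above)) max(partner_total[above[1]], probe_conc / 2)
         else max(partner_total)
  fail <- structure(list(kd_equb = NA_real_, kd_se = NA_real_,
                         r_free = NA_real_, r_bound = NA_real_,
                         converged = FALSE, poorly_determined = TRUE),
                    class = "equilibrium_result")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      anisotropy ~ rf + (rb - rf) *
        fraction_bound(partner_total, probe_conc, exp(lkd)),
      start = list(rf = rf0, rb = rb0, lkd = log(kd0)),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  co <- summary(fit)$coefficients
  kd <- exp(co["lkd", "Estimate"])
  kd_se <- kd * co["lkd", "Std. Error"]
  structure(list(
    kd_equb = kd, kd_se = kd_se,
    r_free = co["rf", "Estimate"], r_bound = co["rb", "Estimate"],
    converged = TRUE,
    poorly_determined = kd > max(partner_total) ||
      !is.finite(kd_se) || kd_se / kd > 0.5),
    class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("Anisotropy isotherm fit: Kd = %.4g +/- %.2g M%s\n",
              x$kd_equb, x$kd_se,
              if (isTRUE(x$poorly_determined)) " (poorly determined)" else ""))
  cat(sprintf("  r_free = %.4g, r_bound = %.4g\n", x$r_free, x$r_bound))
  invisible(x)
}

#' Default helix/coil mean-residue-ellipticity baselines
#'
#' Standard temperature- and chain-length-dependent baseline forms for the
#' 222 nm mean residue ellipticity (deg cm^2 dmol^-1 residue^-1):
#' helix `(mre_helix_inf + helix_temp_coef * TC) * (1 - helix_length_coef / n)`
#' and coil `mre_coil_0 + coil_temp_coef * TC`, with TC the temperature in
#' degrees Celsius. The constants are configuration with these documented
#' defaults, not measured quantities.
#'
#' @return named list of baseline constants.
#' @export
helix_baselines <- function() {
  list(mre_helix_inf = -44000, helix_temp_coef = 250, helix_length_coef = 3,
       mre_coil_0 = 640, coil_temp_coef = -45)
}

.mre_endpoints <- function(n_residues, temperature, baselines) {
  tc <- temperature - 273.15
  list(helix = (baselines$mre_helix_inf + baselines$helix_temp_coef * tc) *
         (1 - baselines$helix_length_coef / n_residues),
       coil = baselines$mre_coil_0 + baselines$coil_temp_coef * tc)
}

#' Fraction helix from mean residue ellipticity at 222 nm
#'
#' Linear two-state estimator
#' `f_H = (MRE222 - MRE_coil) / (MRE_helix - MRE_coil)` with
#' chain-length- and temperature-dependent baselines (see
#' [helix_baselines()]). Out-of-range results are clipped to \[0, 1\] with
#' a warning.
#'
#' @param mre_222 mean residue ellipticity at 222 nm
#'   (deg cm^2 dmol^-1 residue^-1); vectorized.
#' @param n_residues peptide length (>= 5).
#' @param temperature temperature (K).
#' @param baselines baseline constants, see [helix_baselines()].
#' @return fraction helix in \[0, 1\].
#' @export
estimate_fraction_helix <- function(mre_222, n_residues,
                                    temperature = 298.15,
                                    baselines = helix_baselines()) {
  if (n_residues < 5) stop("'n_residues' must be >= 5", call. = FALSE)
  ep <- .mre_endpoints(n_residues, temperature, baselines)
  f <- (mre_222 - ep$coil) / (ep$helix - ep$coil)
  if (any(f < 0 | f > 1))
    warning("fraction helix outside [0, 1]; clipped", call. = FALSE)
  pmin(pmax(f, 0), 1)
}

#' Inverse of the fraction-helix estimator
#'
#' Maps a fraction helix back to the 222 nm mean residue ellipticity under
#' the same baselines; used by the synthetic CD generator.
#'
#' @inheritParams estimate_fraction_helix
#' @param fraction_helix fraction in \[0, 1\]; vectorized.
#' @return mean residue ellipticity (deg cm^2 dmol^-1 residue^-1).
#' @export
mre_from_fraction_helix <- function(fraction_helix, n_residues,
                                    temperature = 298.15,
                                    baselines = helix_baselines()) {
  if (n_residues < 5) stop("'n_residues' must be >= 5", call. = FALSE)
  ep <- .mre_endpoints(n_residues, temperature, baselines)
  ep$coil + fraction_helix * (ep$helix - ep$coil)
}
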