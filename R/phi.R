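#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
R_KCAL <- 1.987e-3

#' Kinetic dissociation constant from fitted rate constants
#'
#' `Kd_Kin = k_diss / k_ass,fast`, with first-order (delta-method) error
#' propagation on the ratio:
#' `relSE^2 = relSE(k_diss)^2 + relSE(k_ass_fast)^2`.
#'
#' @param k_diss apparent dissociation rate constant (s^-1), > 0.
#' @param k_ass_fast fast association rate constant (M^-1 s^-1), > 0.
#' @param k_diss_se,k_ass_fast_se standard errors (same units), >= 0.
#' @return list with `value` (M) and `se`.
#' @export
kd_kin <- function(k_diss, k_ass_fast, k_diss_se = 0, k_ass_fast_se = 0) {
  if (k_diss <= 0 || k_ass_fast <= 0)
    stop("rate constants must be > 0", call. = FALSE)
  if (k_diss_se < 0 || k_ass_fast_se < 0)
    stop("standard errors must be >= 0", call. = FALSE)
  v <- k_diss / k_ass_fast
  list(value = v,
       se = v * sqrt((k_diss_se / k_diss)^2 +
                       (k_ass_fast_se / k_ass_fast)^2))
}

#' Binding free-energy change upon mutation
#'
#' `ddG = R T ln(Kd_mut / Kd_ref)` with R = 1.987e-3 kcal mol^-1 K^-1;
#' positive values are destabilizing. The SE follows from propagation of
#' the log: `se = R T sqrt(relSE(mut)^2 + relSE(ref)^2)`.
#'
#' @param kd_mut,kd_ref dissociation constants (M), > 0.
#' @param temperature temperature (K).
#' @param kd_mut_se,kd_ref_se standard errors (M), >= 0.
#' @return list with `value` (kcal mol^-1) and `se`.
#' @export
delta_delta_g <- function(kd_mut, kd_ref, temperature = 298.15,
                          kd_mut_se = 0, kd_ref_se = 0) {
  if (kd_mut <= 0 || kd_ref <= 0) stop("Kd values must be > 0",
                                       call. = FALSE)
  rt <- R_KCAL * temperature
  list(value = rt * log(kd_mut / kd_ref),
       se = rt * sqrt((kd_mut_se / kd_mut)^2 + (kd_ref_se / kd_ref)^2))
}

#' Phi-value with delta-method error propagation
#'
#' `Phi = ln(k_ass_ref / k_ass_mut) / ln(kd_mut / kd_ref)`. With
#' A the numerator and B the denominator, the propagated SE is
#' `sqrt((sigma_A / B)^2 + (A sigma_B / B^2)^2)` where
#' `sigma_A^2 = relSE(k_ass_ref)^2 + relSE(k_ass_mut)^2` and
#' `sigma_B^2 = relSE(kd_mut)^2 + relSE(kd_ref)^2`; this reduces to
#' `sigma_A / |B|` as A -> 0. The correlation induced by a shared
#' reference is ignored (inputs treated as independent).
#'
#' @param k_ass_ref,k_ass_mut fast association rate constants
#'   (M^-1 s^-1), > 0.
#' @param kd_mut,kd_ref dissociation constants (M), > 0; must differ.
#' @param k_ass_ref_se,k_ass_mut_se,kd_mut_se,kd_ref_se standard errors.
#' @return list with `value` (unitless) and `se`.
#' @export
phi_value <- function(k_ass_ref, k_ass_mut, kd_mut, kd_ref,
                      k_ass_ref_se = 0, k_ass_mut_se = 0,
                      kd_mut_se = 0, kd_ref_se = 0) {
  if (any(c(k_ass_ref, k_ass_mut, kd_mut, kd_ref) <= 0))
    stop("all rate and equilibrium constants must be > 0", call. = FALSE)
  B <- log(kd_mut / kd_ref)
  if (B == 0)
    stop("undefined Phi: kd_mut equals kd_ref (zero denominator)",
         call. = FALSE)
  A <- log(k_ass_ref / k_ass_mut)
  sA <- sqrt((k_ass_ref_se / k_ass_ref)^2 + (k_ass_mut_se / k_ass_mut)^2)
  sB <- sqrt((kd_mut_se / kd_mut)^2 + (kd_ref_se / kd_ref)^2)
  list(value = A / B,
       se = sqrt((sA / B)^2 + (A * sB / B^2)^2))
}

#' Average of equilibrium and kinetic Phi-values
#'
#' Arithmetic mean with half-width SE combination
#' `sqrt(se1^2 + se2^2) / 2`.
#'
#' @param phi_equb,phi_kin lists with `value` and `se` (from
#'   [phi_value()]).
#' @return list with `value` and `se`.
#' @export
phi_average <- function(phi_equb, phi_kin) {
  list(value = mean(c(phi_equb$value, phi_kin$value)),
       se = sqrt(phi_equb$se^2 + phi_kin$se^2) / 2)
}

#' Dual-branch reporting filter on ddG
#'
#' A variant's Phi-value is reportable only when both the equilibrium and
#' the kinetic destabilization reach the threshold (inclusive boundary).
#' Stabilizing mutations (negative ddG) are never reportable.
#'
#' @param ddg_equb,ddg_kin destabilization free energies (kcal mol^-1).
#'   `NA` fails the filter.
#' @param threshold reporting threshold (kcal mol^-1), default 0.34.
#' @return logical vector.
#' @export
apply_report_filter <- function(ddg_equb, ddg_kin, threshold = 0.34) {
  out <- !is.na(ddg_equb) & !is.na(ddg_kin) &
    ddg_equb >= threshold & ddg_kin >= threshold
  out
}

#' Kinetic/equilibrium ddG consistency check
#'
#' Flags variants whose equilibrium and kinetic ddG disagree by more than
#' `tol_mult` combined standard errors (with a small absolute floor so
#' that machine-precision differences on noiseless data never flag).
#' Flagged variants are excluded from the reported transition-state
#' pattern.
#'
#' @param ddg_equb,ddg_kin ddG values (kcal mol^-1).
#' @param ddg_equb_se,ddg_kin_se their standard errors.
#' @param tol_mult multiple of the combined SE tolerated (default 2).
#' @param floor absolute tolerance floor (kcal mol^-1).
#' @return logical vector: `TRUE` = consistent.
#' @export
consistency_check <- function(ddg_equb, ddg_kin, ddg_equb_se = 0,
                              ddg_kin_se = 0, tol_mult = 2,
                              floor = 1e-4) {
  tol <- pmax(tol_mult * sqrt(ddg_equb_se^2 + ddg_kin_se^2), floor)
  abs(ddg_equb - ddg_kin) <= tol
}

#' Transition-state class from a Phi-value
#'
#' Default rule: `Phi + SE < 0` -> `nonnative_candidate` (the mutation
#' speeds transition-state formation); `|Phi| <= unstructured` ->
#' `unstructured`; `Phi <= structured` -> `weakly_structured`; above ->
#' `structured`. Thresholds are interpretive configuration.
#'
#' @param phi Phi-values (vectorized).
#' @param phi_se standard errors.
#' @param thresholds list with elements `unstructured` (default 0.1) and
#'   `structured` (default 0.5).
#' @return character vector of class labels.
#' @export
classify_transition_state <- function(phi, phi_se,
                                      thresholds = list(unstructured = 0.1,
                                                        structured = 0.5)) {
  out <- rep(NA_character_, length(phi))
  ok <- is.finite(phi)
  # the tiny offset keeps machine-precision zeros (noiseless data) from
  # classifying as significantly negative
  out[ok & (phi + phi_se) < -1e-8] <- "nonnative_candidate"
  rest <- ok & is.na(out)
  out[rest & abs(phi) <= thresholds$unstructured] <- "unstructured"
  rest <- ok & is.na(out)
  out[rest & phi <= thresholds$structured] <- "weakly_structured"
  rest <- ok & is.na(out)
  out[rest] <- "structured"
  out
}

#' Composite surface-mutation Phi-result (Ala reference)
#'
#' For solvent-exposed positions probed by Ala-Gly scanning, ddG and Phi
#' for the helix-probing step are computed with the Ala variant as the
#' reference state rather than wild-type, on both the equilibrium and
#' kinetic branches.
#'
#' @param ala,gly single-row data.frames (or lists) carrying the fitted
#'   quantities `k_ass_fast`, `k_ass_fast_se`, `k_diss`, `k_diss_se`,
#'   `kd_equb`, `kd_equb_se` plus `position`.
#' @param temperature temperature (K).
#' @param ddg_threshold reporting threshold (kcal mol^-1).
#' @param consistency_mult tolerance multiple for [consistency_check()].
#' @return one-row data.frame of Phi-result fields (see [phi_report()]).
#' @export
composite_ala_gly <- function(ala, gly, temperature = 298.15,
                              ddg_threshold = 0.34, consistency_mult = 2) {
  if (!identical(ala$position, gly$position))
    stop("Ala and Gly records must share a position", call. = FALSE)
  .phi_row(mut = gly, ref = ala, temperature = temperature,
           ddg_threshold = ddg_threshold,
           consistency_mult = consistency_mult)
}

# Core per-variant computation: mutant vs reference record.
# Both records carry k_ass_fast(_se), k_diss(_se), kd_equb(_se).
.phi_row <- function(mut, ref, temperature, ddg_threshold,
                     consistency_mult) {
  na <- list(value = NA_real_, se = NA_real_)
  has_kin_mut <- is.finite(mut$k_ass_fast) && is.finite(mut$k_diss)
  has_kin_ref <- is.finite(ref$k_ass_fast) && is.finite(ref$k_diss)
  has_eq <- is.finite(mut$kd_equb) && is.finite(ref$kd_equb)

  kk_mut <- if (has_kin_mut)
    kd_kin(mut$k_diss, mut$k_ass_fast, mut$k_diss_se, mut$k_ass_fast_se)
  else na
  kk_ref <- if (has_kin_ref)
    kd_kin(ref$k_diss, ref$k_ass_fast, ref$k_diss_se, ref$k_ass_fast_se)
  else na

  dg_eq <- if (has_eq)
    delta_delta_g(mut$kd_equb, ref$kd_equb, temperature,
                  mut$kd_equb_se, ref$kd_equb_se)
  else na
  dg_kin <- if (has_kin_mut && has_kin_ref)
    delta_delta_g(kk_mut$value, kk_ref$value, temperature,
                  kk_mut$se, kk_ref$se)
  else na

  safe_phi <- function(kd_mut, kd_ref, kd_mut_se, kd_ref_se) {
    if (!is.finite(mut$k_ass_fast) || !is.finite(ref$k_ass_fast) ||
        !is.finite(kd_mut) || !is.finite(kd_ref) || kd_mut == kd_ref)
      return(na)
    phi_value(ref$k_ass_fast, mut$k_ass_fast, kd_mut, kd_ref,
              ref$k_ass_fast_se, mut$k_ass_fast_se, kd_mut_se, kd_ref_se)
  }
  p_eq <- safe_phi(mut$kd_equb, ref$kd_equb, mut$kd_equb_se,
                   ref$kd_equb_se)
  p_kin <- safe_phi(kk_mut$value, kk_ref$value, kk_mut$se, kk_ref$se)
  p_avg <- if (is.finite(p_eq$value) && is.finite(p_kin$value))
    phi_average(p_eq, p_kin)
  else na

  reportable <- apply_report_filter(dg_eq$value, dg_kin$value,
                                    ddg_threshold)
  consistent <- if (is.finite(dg_eq$value) && is.finite(dg_kin$value))
    consistency_check(dg_eq$value, dg_kin$value, dg_eq$se, dg_kin$se,
                      consistency_mult)
  else NA
  data.frame(
    kd_kin = kk_mut$value, kd_kin_se = kk_mut$se,
    ddg_equb = dg_eq$value, ddg_equb_se = dg_eq$se,
    ddg_kin = dg_kin$value, ddg_kin_se = dg_kin$se,
    phi_equb = p_eq$value, phi_equb_se = p_eq$se,
    phi_kin = p_kin$value, phi_kin_se = p_kin$se,
    phi_average = p_avg$value, phi_average_se = p_avg$se,
    reportable = reportable, consistent = consistent)
}
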