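#' Induced-fit three-state kinetic scheme
#'
#' Constructs the microscopic rate-constant set of the induced-fit binding
#' scheme A + B <-> C <-> D, where A is the labelled peptide, B the partner
#' protein (in pseudo-first-order excess), C the initial encounter complex
#' and D the folded bound state.
#'
#' The two-state limit (no bound-state isomerization) is encoded by
#' `k_f = k_u = 0`.
#'
#' @param k_on bimolecular association rate constant (M^-1 s^-1).
#' @param k_off encounter-complex dissociation rate constant (s^-1).
#' @param k_f forward isomerization rate C -> D (s^-1).
#' @param k_u reverse isomerization rate D -> C (s^-1).
#' @return An object of class `kinetic_scheme`.
#' @examples
#' sc <- kinetic_scheme(k_on = 1e6, k_off = 1, k_f = 5, k_u = 0.5)
#' eigen_rates(sc, 1e-5)
#' equilibrium_kd(sc)
#' @export
kinetic_scheme <- function(k_on, k_off, k_f = 0, k_u = 0) {
  for (nm in c("k_on", "k_off", "k_f", "k_u")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (k_on <= 0 || k_off <= 0)
    stop("invalid scheme: k_on and k_off must be strictly positive",
         call. = FALSE)
  if (k_f < 0 || k_u < 0)
    stop("invalid scheme: k_f and k_u must be non-negative", call. = FALSE)
  structure(list(k_on = k_on, k_off = k_off, k_f = k_f, k_u = k_u),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Induced-fit kinetic scheme (A + B <-> C <-> D)\n")
  cat(sprintf("  k_on  = %.4g M^-1 s^-1\n", x$k_on))
  cat(sprintf("  k_off = %.4g s^-1\n", x$k_off))
  cat(sprintf("  k_f   = %.4g s^-1\n", x$k_f))
  cat(sprintf("  k_u   = %.4g s^-1\n", x$k_u))
  if (is_two_state(x)) {
    cat("  (two-state limit)\n")
  } else if (x$k_u > 0) {
    cat(sprintf("  Kd (equilibrium) = %.4g M\n", equilibrium_kd(x)))
  }
  invisible(x)
}

#' @rdname kinetic_scheme
#' @param x object to test.
#' @export
is_two_state <- function(x) {
  stopifnot(inherits(x, "kinetic_scheme"))
  x$k_f == 0 && x$k_u == 0
}

.assert_scheme <- function(scheme) {
  if (!inherits(scheme, "kinetic_scheme"))
    stop("'scheme' must be a kinetic_scheme object", call. = FALSE)
  invisible(scheme)
}

#' Rate matrix of the bound-species subsystem
#'
#' 2x2 generator matrix for d/dt (C, D) under pseudo-first-order conditions
#' with the conservation U = total - C - D substituted (species expressed as
#' fractions of total labelled peptide). Used internally and by numerical
#' oracles.
#'
#' @param scheme a [kinetic_scheme()].
#' @param partner_conc partner concentration (M).
#' @return 2x2 numeric matrix.
#' @keywords internal
#' @export
rate_matrix <- function(scheme, partner_conc) {
  .assert_scheme(scheme)
  kb <- scheme$k_on * partner_conc
  matrix(c(-(kb + scheme$k_off + scheme$k_f), scheme$k_f,
           scheme$k_u - kb, -scheme$k_u),
         nrow = 2L, dimnames = list(c("C", "D"), c("C", "D")))
}

#' Relaxation rates of the scheme under pseudo-first-order conditions
#'
#' Closed-form eigen-rates of the two-species (C, D) linear system with
#' apparent binding rate a = k_on * B + k_off:
#' lambda_pm = (s +/- sqrt(s^2 - 4 p)) / 2 with s = a + k_f + k_u and
#' p = a (k_f + k_u) - k_off k_f. The larger root is the observed fast
#' association phase, linear in B at high B with slope k_on; the smaller
#' root is the concentration-insensitive slow phase, bounded by k_f + k_u.
#'
#' @param scheme a [kinetic_scheme()].
#' @param partner_conc partner concentration(s) in M; vectorized.
#' @return data.frame with columns `partner_conc`, `lambda_fast`,
#'   `lambda_slow` (s^-1).
#' @export
eigen_rates <- function(scheme, partner_conc) {
  .assert_scheme(scheme)
  if (any(!is.finite(partner_conc)) || any(partner_conc < 0))
    stop("'partner_conc' must be finite and >= 0", call. = FALSE)
  a <- scheme$k_on * partner_conc + scheme$k_off
  s <- a + scheme$k_f + scheme$k_u
  p <- a * (scheme$k_f + scheme$k_u) - scheme$k_off * scheme$k_f
  disc <- s^2 - 4 * p
  if (any(disc < -1e-9 * s^2))
    stop("internal error: complex relaxation rates for a real scheme",
         call. = FALSE)
  disc <- pmax(disc, 0)
  root <- sqrt(disc)
  data.frame(partner_conc = partner_conc,
             lambda_fast = (s + root) / 2,
             lambda_slow = (s - root) / 2)
}

#' Overall equilibrium dissociation constant of the scheme
#'
#' Detailed balance over the two bound states gives
#' Kd = (k_off / k_on) / (1 + k_f / k_u); the two-state limit returns
#' k_off / k_on.
#'
#' @param scheme a [kinetic_scheme()].
#' @return dissociation constant (M).
#' @export
equilibrium_kd <- function(scheme) {
  .assert_scheme(scheme)
  if (is_two_state(scheme)) return(scheme$k_off / scheme$k_on)
  if (scheme$k_u == 0)
    stop("infinite affinity: k_u = 0 with k_f > 0 traps the bound state",
         call. = FALSE)
  (scheme$k_off / scheme$k_on) / (1 + scheme$k_f / scheme$k_u)
}

#' Apparent dissociation rate under a competitor trap
#'
#' Model prediction of the competition-dissociation asymptote: with
#' rebinding blocked, the bound subsystem (C, D) drains through C at k_off
#' and the observed long-time rate is the smaller eigenvalue of that
#' system, i.e. the smaller root of
#' lambda^2 - (k_off + k_f + k_u) lambda + k_off k_u = 0.
#' For the two-state scheme this is k_off exactly. Note the root is bounded
#' above by k_u when k_off dominates: escape from the folded bound state
#' becomes rate limiting.
#'
#' @param scheme a [kinetic_scheme()].
#' @return apparent dissociation rate constant (s^-1).
#' @export
apparent_koff <- function(scheme) {
  .assert_scheme(scheme)
  if (is_two_state(scheme)) return(scheme$k_off)
  s <- scheme$k_off + scheme$k_f + scheme$k_u
  p <- scheme$k_off * scheme$k_u
  disc <- s^2 - 4 * p
  if (disc < 0) stop("internal error: complex trap eigenvalues", call. = FALSE)
  (s - sqrt(disc)) / 2
}

#' Kinetic dissociation constant of the scheme
#'
#' The quantity the stopped-flow analysis estimates as
#' k_diss / k_ass,fast: here predicted from the microscopic constants as
#' [apparent_koff()] / k_on. For three-state schemes it differs from
#' [equilibrium_kd()]; the two agree exactly in the two-state limit and
#' nearly so when k_off << k_f + k_u.
#'
#' @param scheme a [kinetic_scheme()].
#' @return dissociation constant (M).
#' @export
kinetic_kd_scheme <- function(scheme) {
  apparent_koff(scheme) / scheme$k_on
}
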