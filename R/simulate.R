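#' Analytic species fractions of the bound subsystem
#'
#' Exact solution of d/dt (C, D) = M (C, D) + b for the pseudo-first-order
#' scheme, as fractions of total labelled peptide. `mode = "association"`
#' starts from all-unbound; `mode = "dissociation"` starts from the
#' equilibrium C:D ratio of the scheme (all bound) and is usually combined
#' with `partner_conc = 0` to represent the competitor trap.
#'
#' @param scheme a [kinetic_scheme()].
#' @param partner_conc partner concentration (M), scalar.
#' @param times strictly increasing time grid (s).
#' @param mode `"association"` or `"dissociation"`.
#' @return matrix with columns `C` and `D` (fractions), one row per time.
#' @export
species_fractions <- function(scheme, partner_conc, times,
                              mode = c("association", "dissociation")) {
  .assert_scheme(scheme)
  mode <- match.arg(mode)
  if (length(partner_conc) != 1L || !is.finite(partner_conc) ||
      partner_conc < 0)
    stop("'partner_conc' must be a single number >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing",
                                  call. = FALSE)
  x0 <- switch(mode,
    association = c(0, 0),
    dissociation = {
      if (is_two_state(scheme)) c(1, 0)
      else c(scheme$k_u, scheme$k_f) / (scheme$k_f + scheme$k_u)
    })
  kb <- scheme$k_on * partner_conc

  if (is_two_state(scheme)) {
    # scalar solution: D stays 0, C relaxes at a = k_on B + k_off
    a <- kb + scheme$k_off
    cinf <- kb / a
    C <- cinf + (x0[1] - cinf) * exp(-a * times)
    return(cbind(C = C, D = rep(0, length(times))))
  }

  M <- rate_matrix(scheme, partner_conc)
  b <- c(kb, 0)
  # det(M) = a (k_f + k_u) - k_off k_f > 0 whenever k_u > 0, so the
  # particular solution is well defined
  xinf <- solve(M, -b)
  eg <- eigen(M)
  co <- solve(eg$vectors, x0 - xinf)
  ex <- exp(outer(times, Re(eg$values)))
  X <- sweep(ex, 2L, co, `*`) %*% t(Re(eg$vectors))
  X <- sweep(X, 2L, xinf, `+`)
  colnames(X) <- c("C", "D")
  X
}

#' Simulate pseudo-first-order fluorescence time traces
#'
#' Forward model for stopped-flow association experiments: the exact
#' two-exponential solution of the scheme starting from all-unbound
#' labelled peptide, converted to a signal via per-species coefficients,
#' plus i.i.d. Gaussian noise. Identical seeds give identical traces.
#'
#' @param scheme a [kinetic_scheme()].
#' @param partner_concs partner concentrations (M), one trace per value.
#' @param amplitudes named numeric vector of per-species signal
#'   coefficients `c(U = , C = , D = )` (signal units per unit fraction).
#' @param time_grid strictly increasing times (s).
#' @param noise_sd standard deviation of additive Gaussian noise (signal
#'   units); 0 gives the analytic trace.
#' @param seed integer seed for the noise; `NULL` leaves the RNG state
#'   alone.
#' @param probe_conc labelled-peptide concentration (M), used only for the
#'   pseudo-first-order check: partner concentrations below
#'   `pfo_ratio * probe_conc` trigger a warning.
#' @param pfo_ratio minimum partner/probe excess considered
#'   pseudo-first-order (default 10).
#' @param mode passed to [species_fractions()].
#' @return list of data.frames (`time_s`, `signal`), one per concentration,
#'   each with attributes `partner_conc` and `amplitudes`.
#' @export
simulate_traces <- function(scheme, partner_concs, amplitudes,
                            time_grid, noise_sd = 0, seed = NULL,
                            probe_conc = NULL, pfo_ratio = 10,
                            mode = "association") {
  .assert_scheme(scheme)
  if (length(partner_concs) == 0L)
    stop("'partner_concs' must contain at least one concentration",
         call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  if (any(diff(time_grid) <= 0))
    stop("'time_grid' must be strictly increasing", call. = FALSE)
  if (!all(c("U", "C", "D") %in% names(amplitudes)))
    stop("'amplitudes' must be named with U, C and D", call. = FALSE)
  if (!is.null(probe_conc) && any(partner_concs < pfo_ratio * probe_conc))
    warning("partner concentration below ", pfo_ratio,
            "x probe concentration: pseudo-first-order assumption weak",
            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(partner_concs, function(B) {
    X <- species_fractions(scheme, B, time_grid, mode = mode)
    U <- 1 - X[, "C"] - X[, "D"]
    sig <- amplitudes[["U"]] * U + amplitudes[["C"]] * X[, "C"] +
      amplitudes[["D"]] * X[, "D"]
    if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), sd = noise_sd)
    out <- data.frame(time_s = time_grid, signal = as.numeric(sig))
    attr(out, "partner_conc") <- B
    attr(out, "amplitudes") <- amplitudes
    out
  })
}
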