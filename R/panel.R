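#' Default variant truth table for the synthetic mutant panel
#'
#' A fixed design emulating an interface + Ala-Gly-scanning panel on a
#' kinked two-helix disordered peptide: eleven interface X->Ala variants
#' spread over helix A, the interhelical kink and helix B, and six
#' solvent-exposed positions (three per helix) each carried as an Ala and
#' a Gly variant. Ground truth is expressed in the quantities the
#' analysis identifies: the total destabilization `ddg_true`
#' (kcal mol^-1, relative to wild-type) and the fraction of it felt by
#' the association rate, `phi_true`. For Gly rows `phi_true` refers to
#' the composite Ala->Gly step. One strongly destabilized variant
#' carries the amplitude-suppression switch (no usable kinetic signal),
#' and the kink region carries a contiguous patch of negative `phi_true`.
#' All values are synthetic design choices, not measurements.
#'
#' @return data.frame with columns `variant_id`, `position`, `region`,
#'   `site_class`, `substitution`, `ddg_true`, `phi_true`,
#'   `amplitude_suppressed`.
#' @export
default_variant_truth <- function() {
  v <- function(id, pos, region, class, sub, ddg, phi, supp = FALSE)
    data.frame(variant_id = id, position = pos, region = region,
               site_class = class, substitution = sub, ddg_true = ddg,
               phi_true = phi, amplitude_suppressed = supp)
  rbind(
    v("WT",    NA_integer_, NA_character_, NA_character_, "wild_type",
      0, NA_real_),
    # interface X -> Ala
    v("S121A", 121L, "helix_A", "interface", "to_ala", 0.25,  0.30),
    v("R124A", 124L, "helix_A", "interface", "to_ala", 0.60,  0.25),
    v("R125A", 125L, "helix_A", "interface", "to_ala", 0.70,  0.20),
    v("E126A", 126L, "helix_A", "interface", "to_ala", 0.45,  0.30),
    v("L128A", 128L, "kink",    "interface", "to_ala", 1.40, -0.05),
    v("R131A", 131L, "kink",    "interface", "to_ala", 1.60, -0.12),
    v("S133A", 133L, "kink",    "interface", "to_ala", 1.00, -0.08),
    v("Y134A", 134L, "helix_B", "interface", "to_ala", 4.10,  0.10,
      supp = TRUE),
    v("I137A", 137L, "helix_B", "interface", "to_ala", 2.00,  0.25),
    v("L138A", 138L, "helix_B", "interface", "to_ala", 1.80,  0.40),
    v("D140A", 140L, "helix_B", "interface", "to_ala", 1.50,  0.35),
    # solvent-exposed Ala/Gly pairs, three positions per helix
    v("T119A", 119L, "helix_A", "surface", "to_ala", -0.10, 0.10),
    v("T119G", 119L, "helix_A", "surface", "to_gly",  0.10, 0.20),
    v("S120A", 120L, "helix_A", "surface", "to_ala",  0.05, 0.10),
    v("S120G", 120L, "helix_A", "surface", "to_gly",  0.25, 0.20),
    v("Q123A", 123L, "helix_A", "surface", "to_ala",  0.00, 0.10),
    v("Q123G", 123L, "helix_A", "surface", "to_gly",  0.30, 0.25),
    v("K135A", 135L, "helix_B", "surface", "to_ala", -0.05, 0.10),
    v("K135G", 135L, "helix_B", "surface", "to_gly",  0.55, 0.30),
    v("Q136A", 136L, "helix_B", "surface", "to_ala",  0.00, 0.10),
    v("Q136G", 136L, "helix_B", "surface", "to_gly",  0.75, 0.25),
    v("N139A", 139L, "helix_B", "surface", "to_ala",  0.10, 0.10),
    v("N139G", 139L, "helix_B", "surface", "to_gly",  0.35, 0.30))
}

#' Panel configuration for the synthetic generator
#'
#' @param wt_scheme wild-type [kinetic_scheme()]. The default
#'   (`k_on` 4e6 M^-1 s^-1, `k_off` 0.02 s^-1, `k_f` 4 s^-1, `k_u` 1
#'   s^-1) keeps encounter-complex dissociation slow compared with the
#'   bound-state isomerization, the regime in which the kinetic and
#'   equilibrium Kd of the three-state scheme agree closely.
#' @param variants truth table as from [default_variant_truth()].
#' @param temperature temperature (K) used to convert `ddg_true` to Kd
#'   ratios.
#' @return list of class `panel_config`.
#' @export
panel_config <- function(wt_scheme = kinetic_scheme(k_on = 4e6,
                                                    k_off = 0.02,
                                                    k_f = 4, k_u = 1),
                         variants = default_variant_truth(),
                         temperature = 298.15) {
  .assert_scheme(wt_scheme)
  need <- c("variant_id", "position", "region", "site_class",
            "substitution", "ddg_true", "phi_true")
  if (!all(need %in% names(variants)))
    stop("'variants' must carry columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (sum(variants$substitution == "wild_type") != 1L)
    stop("exactly one wild-type row required", call. = FALSE)
  if (is.null(variants$amplitude_suppressed))
    variants$amplitude_suppressed <- FALSE
  structure(list(wt_scheme = wt_scheme, variants = variants,
                 temperature = temperature),
            class = "panel_config")
}

# invert the Phi definition: given a reference scheme, the Kd ratio and
# phi, place phi of the destabilization on association and the remainder
# on the dissociation side, holding k_f and k_u at reference values
.scheme_from_truth <- function(ref_scheme, kd_ratio, phi) {
  k_on <- ref_scheme$k_on * kd_ratio^(-phi)
  kd_ref <- equilibrium_kd(ref_scheme)
  kd_mut <- kd_ref * kd_ratio
  fold <- if (is_two_state(ref_scheme)) 1
          else 1 + ref_scheme$k_f / ref_scheme$k_u
  k_off <- kd_mut * k_on * fold
  if (k_on <= 0 || k_off <= 0)
    stop("ddg_true/phi_true combination yields non-positive rates",
         call. = FALSE)
  kinetic_scheme(k_on, k_off, ref_scheme$k_f, ref_scheme$k_u)
}

#' Build a synthetic mutant panel with ground truth
#'
#' Converts per-variant truth (`ddg_true`, `phi_true`) into microscopic
#' rate constants by inverting the Phi definition: the association rate
#' scales as `(Kd_mut/Kd_ref)^(-phi_true)` and the residual
#' destabilization is placed on the encounter-complex dissociation rate,
#' with the isomerization rates `k_f`, `k_u` held at wild-type values
#' (the slow association phase is insensitive to mutation). Gly rows at
#' surface positions are built against their Ala sibling, so the
#' composite Ala->Gly step carries `phi_true` exactly; their total Kd
#' still satisfies `ddg_true` relative to wild-type.
#'
#' @param config a [panel_config()].
#' @return object of class `panel_truth`: the truth table augmented with
#'   per-variant scheme parameters, `kd_true` (equilibrium),
#'   `kdiss_app_true` (competition asymptote) and `k_ass_fast_true`
#'   (= k_on), plus the wild-type scheme and temperature.
#' @export
make_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  v <- config$variants
  rt <- R_KCAL * config$temperature
  wt <- config$wt_scheme

  schemes <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    if (row$substitution == "wild_type") {
      schemes[[i]] <- wt
    } else if (row$substitution == "to_gly" &&
               row$site_class == "surface") {
      ala <- which(v$position %in% row$position &
                     v$substitution == "to_ala" &
                     v$site_class == "surface")
      if (length(ala) != 1L)
        stop("surface Gly variant at position ", row$position,
             " has no unique Ala sibling", call. = FALSE)
      ala_scheme <- schemes[[ala]]
      if (is.null(ala_scheme))
        stop("order the truth table with Ala rows before Gly rows",
             call. = FALSE)
      step_ratio <- exp((row$ddg_true - v$ddg_true[ala]) / rt)
      schemes[[i]] <- .scheme_from_truth(ala_scheme, step_ratio,
                                         row$phi_true)
    } else {
      schemes[[i]] <- .scheme_from_truth(wt, exp(row$ddg_true / rt),
                                         row$phi_true)
    }
  }
  v$k_on <- vapply(schemes, function(s) s$k_on, 0)
  v$k_off <- vapply(schemes, function(s) s$k_off, 0)
  v$k_f <- vapply(schemes, function(s) s$k_f, 0)
  v$k_u <- vapply(schemes, function(s) s$k_u, 0)
  v$kd_true <- vapply(schemes, equilibrium_kd, 0)
  v$kdiss_app_true <- vapply(schemes, apparent_koff, 0)
  v$k_ass_fast_true <- v$k_on
  structure(list(variants = v, wt_scheme = wt,
                 temperature = config$temperature),
            class = "panel_truth")
}

#' @export
print.panel_truth <- function(x, ...) {
  cat(sprintf("Synthetic mutant panel: %d variants (T = %.2f K)\n",
              nrow(x$variants) - 1L, x$temperature))
  print(x$variants[, c("variant_id", "region", "site_class",
                       "substitution", "ddg_true", "phi_true",
                       "kd_true")], digits = 3)
  invisible(x)
}

#' Retrieve the kinetic scheme of one panel variant
#'
#' @param panel a [make_panel()] result.
#' @param variant_id variant identifier.
#' @return a [kinetic_scheme()].
#' @export
panel_scheme <- function(panel, variant_id) {
  stopifnot(inherits(panel, "panel_truth"))
  i <- match(variant_id, panel$variants$variant_id)
  if (is.na(i)) stop("unknown variant: ", variant_id, call. = FALSE)
  r <- panel$variants[i, ]
  kinetic_scheme(r$k_on, r$k_off, r$k_f, r$k_u)
}

#' Parameter-recovery study panel
#'
#' A 20-variant two-state panel for estimator-recovery studies:
#' `ddg_true` spans `ddg_range` on an even grid while `phi_true` runs
#' anti-monotonically over `phi_range`, which keeps every variant's
#' observed rates inside the simulated stopped-flow window (strong
#' destabilization never coincides with rate-enhancing negative Phi).
#' The two-state scheme is used because kinetic and equilibrium Kd
#' definitions coincide there exactly, making recovery error purely
#' estimator error.
#'
#' @param n_variants number of mutants (default 20).
#' @param ddg_range destabilization range (kcal mol^-1).
#' @param phi_range Phi range, assigned in reverse order of `ddg_true`.
#' @param wt_scheme two-state wild-type scheme.
#' @param temperature temperature (K).
#' @return a [panel_config()].
#' @export
recovery_panel_config <- function(n_variants = 20,
                                  ddg_range = c(0.4, 4.1),
                                  phi_range = c(-0.2, 0.5),
                                  wt_scheme = kinetic_scheme(k_on = 4e6,
                                                             k_off = 0.2),
                                  temperature = 298.15) {
  ddg <- seq(ddg_range[1], ddg_range[2], length.out = n_variants)
  phi <- seq(phi_range[2], phi_range[1], length.out = n_variants)
  regions <- rep(c("helix_A", "kink", "helix_B"), length.out = n_variants)
  variants <- rbind(
    data.frame(variant_id = "WT", position = NA_integer_,
               region = NA_character_, site_class = NA_character_,
               substitution = "wild_type", ddg_true = 0,
               phi_true = NA_real_, amplitude_suppressed = FALSE),
    data.frame(variant_id = sprintf("M%02dA", seq_len(n_variants)),
               position = 100L + seq_len(n_variants), region = regions,
               site_class = "interface", substitution = "to_ala",
               ddg_true = ddg, phi_true = phi,
               amplitude_suppressed = FALSE))
  panel_config(wt_scheme = wt_scheme, variants = variants,
               temperature = temperature)
}

#' Dissociation-dominated pattern panel
#'
#' A two-state panel emulating the qualitative mutant-series structure of
#' a coupled folding-and-binding Phi analysis: mutational effects
#' concentrated in the dissociation rate (`phi_true` = 0 outside the
#' kink), a contiguous patch of negative `phi_true` in the interhelical
#' kink, and destabilizations spanning roughly 0.4-2.2 kcal/mol. Used for
#' linear free-energy, Kd-agreement and transition-state-pattern
#' analyses.
#'
#' @param wt_scheme two-state wild-type scheme.
#' @param temperature temperature (K).
#' @return a [panel_config()].
#' @export
lfe_panel_config <- function(wt_scheme = kinetic_scheme(k_on = 4e6,
                                                        k_off = 0.2),
                             temperature = 298.15) {
  spec <- list(
    helix_A = list(pos = 121:125, ddg = c(0.4, 0.55, 0.7, 0.85, 1.0),
                   phi = rep(0, 5)),
    kink = list(pos = 128:130, ddg = c(1.2, 1.5, 1.8),
                phi = c(-0.08, -0.10, -0.06)),
    helix_B = list(pos = 134:139,
                   ddg = c(1.3, 1.45, 1.75, 1.9, 2.05, 2.2),
                   phi = rep(0, 6)))
  rows <- lapply(names(spec), function(rg) {
    s <- spec[[rg]]
    data.frame(variant_id = sprintf("P%dA", s$pos), position = s$pos,
               region = rg, site_class = "interface",
               substitution = "to_ala", ddg_true = s$ddg,
               phi_true = s$phi, amplitude_suppressed = FALSE)
  })
  variants <- rbind(
    data.frame(variant_id = "WT", position = NA_integer_,
               region = NA_character_, site_class = NA_character_,
               substitution = "wild_type", ddg_true = 0,
               phi_true = NA_real_, amplitude_suppressed = FALSE),
    do.call(rbind, rows))
  panel_config(wt_scheme = wt_scheme, variants = variants,
               temperature = temperature)
}
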