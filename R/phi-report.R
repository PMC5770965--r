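.find_wild_type <- function(rates) {
  wt <- which(rates$substitution == "wild_type")
  if (length(wt) == 0L)
    stop("no wild-type row in the panel (substitution == 'wild_type')",
         call. = FALSE)
  if (length(wt) > 1L)
    stop("more than one wild-type row in the panel; exactly one required",
         call. = FALSE)
  wt
}

#' Panel-level Phi-value report
#'
#' Assembles the full transition-state analysis from a per-variant
#' rate/equilibrium table: Kd_Kin, equilibrium and kinetic ddG, Phi
#' values on both branches with propagated SEs, the dual-branch reporting
#' filter, the kinetic/equilibrium consistency flag, transition-state
#' classes and a per-region summary. Interface variants are computed
#' against wild-type; solvent-exposed Ala/Gly pairs yield one composite
#' row per position with the Ala variant as reference.
#'
#' @param rates data.frame with one row per variant carrying at least
#'   `variant_id`, `position`, `region` (`helix_A`/`kink`/`helix_B`),
#'   `site_class` (`interface`/`surface`), `substitution` (`to_ala`,
#'   `to_gly` or `wild_type`), `k_ass_fast`, `k_ass_fast_se`, `k_diss`,
#'   `k_diss_se`, `kd_equb`, `kd_equb_se`. Missing kinetic or equilibrium
#'   quantities are carried as `NA` and fail the filter rather than
#'   erroring.
#' @param temperature temperature (K).
#' @param ddg_threshold reporting threshold (kcal mol^-1), default 0.34.
#' @param consistency_mult tolerance multiple for [consistency_check()].
#' @param class_thresholds see [classify_transition_state()].
#' @param quiet suppress the per-run count message.
#' @return list of class `phi_report` with elements `phi_table`
#'   (one row per interface variant and per surface position),
#'   `region_summary`, `n_in`, `n_reportable`, `temperature`,
#'   `ddg_threshold`.
#' @export
phi_report <- function(rates, temperature = 298.15, ddg_threshold = 0.34,
                       consistency_mult = 2,
                       class_thresholds = list(unstructured = 0.1,
                                               structured = 0.5),
                       quiet = FALSE) {
  stopifnot(is.data.frame(rates))
  wt <- rates[.find_wild_type(rates), ]
  muts <- rates[rates$substitution != "wild_type", , drop = FALSE]

  rows <- list()
  iface <- muts[muts$site_class == "interface", , drop = FALSE]
  for (i in seq_len(nrow(iface))) {
    v <- iface[i, ]
    r <- .phi_row(v, wt, temperature, ddg_threshold, consistency_mult)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(variant_id = v$variant_id, position = v$position,
                       region = v$region, site_class = "interface",
                       comparison = "vs_wild_type"), r)
  }

  surf <- muts[muts$site_class == "surface", , drop = FALSE]
  for (pos in unique(surf$position)) {
    ala <- surf[surf$position == pos & surf$substitution == "to_ala", ]
    gly <- surf[surf$position == pos & surf$substitution == "to_gly", ]
    if (nrow(ala) != 1L || nrow(gly) != 1L) {
      warning("surface position ", pos,
              " lacks a complete Ala/Gly pair; skipped", call. = FALSE)
      next
    }
    r <- composite_ala_gly(ala, gly, temperature, ddg_threshold,
                           consistency_mult)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(variant_id = paste0(gly$variant_id, "_composite"),
                       position = pos, region = gly$region,
                       site_class = "surface",
                       comparison = "gly_vs_ala"), r)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  use <- tab$reportable & !is.na(tab$consistent) & tab$consistent
  tab$ts_class <- NA_character_
  tab$ts_class[use] <- classify_transition_state(
    tab$phi_average[use], tab$phi_average_se[use], class_thresholds)

  reg <- lapply(split(tab[use, , drop = FALSE], tab$region[use]),
                function(d) {
                  data.frame(region = d$region[1], n = nrow(d),
                             phi_mean = mean(d$phi_average),
                             phi_min = min(d$phi_average),
                             phi_max = max(d$phi_average),
                             n_negative = sum(d$ts_class ==
                                                "nonnative_candidate"))
                })
  region_summary <- do.call(rbind, reg)
  rownames(region_summary) <- NULL

  out <- structure(list(phi_table = tab, region_summary = region_summary,
                        n_in = nrow(muts), n_reportable = sum(tab$reportable),
                        temperature = temperature,
                        ddg_threshold = ddg_threshold),
                   class = "phi_report")
  if (!quiet)
    message(sprintf("phi_report: %d variants in, %d reportable Phi-values",
                    out$n_in, out$n_reportable))
  out
}

#' @export
print.phi_report <- function(x, ...) {
  cat(sprintf("Phi-value report: %d variants, %d reportable (ddG >= %.2f",
              x$n_in, x$n_reportable, x$ddg_threshold),
      "kcal/mol on both branches)\n")
  print(x$phi_table[, c("variant_id", "region", "site_class", "ddg_equb",
                        "ddg_kin", "phi_average", "phi_average_se",
                        "reportable", "consistent", "ts_class")],
        digits = 3)
  cat("\nRegion summary (reportable & consistent):\n")
  print(x$region_summary, digits = 3)
  invisible(x)
}

#' Linear free-energy table and slopes
#'
#' Per-variant log10 quantities plus the two regression slopes that
#' partition stability changes between association and dissociation:
#' log10 k_diss vs log10 Kd (slope 1 when all mutational effect is in
#' dissociation) and log10 k_ass,fast vs log10 Kd (slope 0 in that case,
#' -1 when all effect is in association).
#'
#' @param rates per-variant table as in [phi_report()]; rows lacking any
#'   of `kd_equb`, `k_ass_fast`, `k_diss` are dropped.
#' @return list with `table` (variant_id, log10_kd, log10_k_ass_fast,
#'   log10_k_diss), `slope_kdiss`, `slope_kdiss_se`, `slope_kass`,
#'   `slope_kass_se`.
#' @export
lfe_table <- function(rates) {
  ok <- is.finite(rates$kd_equb) & is.finite(rates$k_ass_fast) &
    is.finite(rates$k_diss)
  d <- rates[ok, , drop = FALSE]
  if (nrow(d) < 3L)
    stop("at least 3 variants with complete rates required", call. = FALSE)
  tab <- data.frame(variant_id = d$variant_id,
                    log10_kd = log10(d$kd_equb),
                    log10_k_ass_fast = log10(d$k_ass_fast),
                    log10_k_diss = log10(d$k_diss))
  f1 <- stats::lm(log10_k_diss ~ log10_kd, data = tab)
  f2 <- stats::lm(log10_k_ass_fast ~ log10_kd, data = tab)
  # noiseless panels fit exactly; the perfect-fit warning is expected
  c1 <- suppressWarnings(summary(f1)$coefficients)
  c2 <- suppressWarnings(summary(f2)$coefficients)
  list(table = tab,
       slope_kdiss = c1["log10_kd", "Estimate"],
       slope_kdiss_se = c1["log10_kd", "Std. Error"],
       slope_kass = c2["log10_kd", "Estimate"],
       slope_kass_se = c2["log10_kd", "Std. Error"])
}

#' Kinetic vs equilibrium Kd agreement table
#'
#' Per-variant ratio `Kd_Kin / Kd_Equb` with log-scale propagated SE and a
#' confidence interval; the summary is the fraction of variants whose
#' interval covers 1 (the identity line of the comparison plot).
#'
#' @param rates per-variant table as in [phi_report()].
#' @param level confidence level (default 0.95).
#' @return list with `table` (variant_id, kd_kin, kd_equb, ratio,
#'   ratio_lo, ratio_hi, covers_one) and `fraction_covering_one`.
#' @export
compare_kd <- function(rates, level = 0.95) {
  ok <- is.finite(rates$kd_equb) & is.finite(rates$k_ass_fast) &
    is.finite(rates$k_diss)
  d <- rates[ok, , drop = FALSE]
  if (nrow(d) == 0L) stop("no variants with both Kd branches",
                          call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  kk <- mapply(function(kd, ka, kds, kas) unlist(kd_kin(kd, ka, kds, kas)),
               d$k_diss, d$k_ass_fast, d$k_diss_se, d$k_ass_fast_se)
  kd_kin_v <- kk["value", ]; kd_kin_se <- kk["se", ]
  ratio <- kd_kin_v / d$kd_equb
  se_ln <- sqrt((kd_kin_se / kd_kin_v)^2 + (d$kd_equb_se / d$kd_equb)^2)
  lo <- ratio * exp(-z * se_ln)
  hi <- ratio * exp(z * se_ln)
  tab <- data.frame(variant_id = d$variant_id, kd_kin = kd_kin_v,
                    kd_kin_se = kd_kin_se, kd_equb = d$kd_equb,
                    kd_equb_se = d$kd_equb_se, ratio = ratio,
                    ratio_lo = lo, ratio_hi = hi,
                    # relative guard keeps zero-width intervals from
                    # noiseless fits from missing the identity line by
                    # solver tolerance alone
                    covers_one = lo <= 1 + 1e-6 & hi >= 1 - 1e-6)
  list(table = tab, fraction_covering_one = mean(tab$covers_one))
}
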