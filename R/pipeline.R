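#' Run configuration
#'
#' Bundles the tunable analysis parameters; a snapshot is written next to
#' every pipeline output. The default temperature is a configuration
#' value, not a measured one.
#'
#' @param temperature temperature (K).
#' @param ddg_threshold reporting threshold (kcal mol^-1).
#' @param consistency_mult kinetic/equilibrium tolerance multiple.
#' @param class_unstructured,class_structured Phi classification
#'   thresholds.
#' @param aicc_margin AICc margin for phase selection.
#' @param seed integer seed for simulation stages.
#' @return list of class `run_config`.
#' @export
run_config <- function(temperature = 298.15, ddg_threshold = 0.34,
                       consistency_mult = 2, class_unstructured = 0.1,
                       class_structured = 0.5, aicc_margin = 2,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

.write_config_snapshot <- function(config, dir) {
  cfg <- config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "run_config.yaml"))
}

# average replicate traces taken on an identical time grid
.average_replicates <- function(reps) {
  if (length(reps) == 1L) return(reps[[1]])
  out <- reps[[1]]
  out$signal <- rowMeans(vapply(reps, function(d) d$signal,
                                numeric(nrow(out))))
  out
}

#' Extract the three rate constants for one variant
#'
#' Full trace-fitting reduction: per concentration, replicate traces are
#' averaged, one- and two-phase fits compared by AICc, and the observed
#' fast (and, when biphasic, slow) rates collected; the fast rates are
#' regressed against concentration for k_ass,fast, the slow rates
#' summarized, and the competition series fit for k_diss. Unusable fits
#' are flagged, not raised.
#'
#' @param traces list over concentrations; each element either a
#'   data.frame with attribute `partner_conc` or a list of replicate
#'   data.frames sharing that attribute.
#' @param competition data.frame (`competitor_conc_M`, `k_obs`,
#'   optionally `k_obs_se`) or `NULL` when the experiment is unavailable.
#' @param aicc_margin AICc margin for [choose_phases()].
#' @return list with `k_ass_fast(_se)`, `intercept(_se)`,
#'   `k_ass_slow(_se)`, `slow_slope_p`, `k_diss(_se)`, `flags`
#'   (character vector) and per-concentration diagnostics in
#'   `$per_conc`.
#' @export
fit_variant_rates <- function(traces, competition = NULL,
                              aicc_margin = 2) {
  flags <- character()
  per_conc <- list()
  for (el in traces) {
    reps <- if (is.data.frame(el)) list(el) else el
    tr <- .average_replicates(reps)
    B <- attr(reps[[1]], "partner_conc")
    f1 <- fit_exponential(tr, 1)
    f2 <- fit_exponential(tr, 2)
    np <- choose_phases(f1, f2, margin = aicc_margin)
    f <- if (np == 2L) f2 else f1
    per_conc[[length(per_conc) + 1L]] <- data.frame(
      partner_conc = B, n_phases = np,
      lambda_fast = f$rates[1], lambda_fast_se = f$rate_se[1],
      lambda_slow = if (np == 2L) f$rates[2] else NA_real_,
      lambda_slow_se = if (np == 2L) f$rate_se[2] else NA_real_,
      converged = f$converged, degenerate = f$degenerate)
  }
  pc <- do.call(rbind, per_conc)
  usable <- pc$converged & !pc$degenerate

  out <- list(k_ass_fast = NA_real_, k_ass_fast_se = NA_real_,
              intercept = NA_real_, intercept_se = NA_real_,
              k_ass_slow = NA_real_, k_ass_slow_se = NA_real_,
              slow_slope_p = NA_real_, k_diss = NA_real_,
              k_diss_se = NA_real_, per_conc = pc)

  if (sum(usable) < 4L) {
    flags <- c(flags, "association_unusable")
  } else {
    assoc <- tryCatch(
      fit_association_series(pc$partner_conc[usable],
                             pc$lambda_fast[usable],
                             pc$lambda_fast_se[usable]),
      error = function(e) NULL)
    if (is.null(assoc)) {
      flags <- c(flags, "association_fit_failed")
    } else {
      out$k_ass_fast <- assoc$k_ass_fast
      out$k_ass_fast_se <- assoc$k_ass_fast_se
      out$intercept <- assoc$intercept
      out$intercept_se <- assoc$intercept_se
    }
    slow_ok <- usable & is.finite(pc$lambda_slow)
    if (sum(slow_ok) >= 4L) {
      sl <- summarize_slow_phase(pc$partner_conc[slow_ok],
                                 pc$lambda_slow[slow_ok])
      out$k_ass_slow <- sl$k_ass_slow
      out$k_ass_slow_se <- sl$k_ass_slow_se
      out$slow_slope_p <- sl$slope_p
    }
  }

  if (is.null(competition)) {
    flags <- c(flags, "no_competition_data")
  } else {
    dis <- tryCatch(
      fit_dissociation_asymptote(competition$competitor_conc_M,
                                 competition$k_obs,
                                 competition$k_obs_se),
      error = function(e) NULL)
    if (is.null(dis) || !isTRUE(dis$converged)) {
      flags <- c(flags, "dissociation_fit_failed")
    } else {
      out$k_diss <- dis$k_diss
      out$k_diss_se <- dis$k_diss_se
      if (isTRUE(dis$saturated)) flags <- c(flags, "k_half_unidentifiable")
    }
  }
  out$flags <- flags
  out
}

#' Fit every variant of a dataset (fit stage)
#'
#' Runs trace fitting, the competition asymptote and the anisotropy
#' isotherm for every variant of a synthetic (or equivalently formatted
#' real) dataset and returns the per-variant rate/equilibrium table the
#' Phi stage consumes. Unusable variants are flagged, never dropped
#' silently.
#'
#' @param ds either a [generate_dataset()] result or the list returned by
#'   [read_dataset()].
#' @param config a [run_config()].
#' @param quiet suppress per-variant progress messages.
#' @return data.frame, one row per variant: metadata columns plus
#'   `k_ass_fast(_se)`, `k_ass_slow(_se)`, `k_diss(_se)`,
#'   `kd_equb(_se)`, `flags` (semicolon-joined, empty when clean).
#' @export
fit_panel <- function(ds, config = run_config(), quiet = TRUE) {
  if (inherits(ds, "panel_dataset")) {
    meta <- ds$panel$variants[, c("variant_id", "position", "region",
                                  "site_class", "substitution")]
    probe <- ds$acq$probe_conc_titration
    get_traces <- function(id) {
      lapply(seq_along(ds$traces[[id]]), function(ci) {
        reps <- ds$traces[[id]][[ci]]
        for (ri in seq_along(reps))
          attr(reps[[ri]], "partner_conc") <- ds$acq$partner_concs[ci]
        reps
      })
    }
  } else {
    meta <- ds$metadata
    probe <- NULL
    get_traces <- function(id) {
      # group flat replicate files by concentration
      tl <- ds$traces[[id]]
      bs <- vapply(tl, function(d) attr(d, "partner_conc"), 0)
      lapply(split(seq_along(tl), factor(bs, levels = unique(bs))),
             function(ix) tl[ix])
    }
  }

  rows <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$variant_id[i]
    if (!quiet) message("fitting ", id)
    rf <- fit_variant_rates(get_traces(id), ds$competition[[id]],
                            aicc_margin = config$aicc_margin)
    tit <- ds$titrations[[id]]
    pr <- if (is.null(probe)) attr(tit, "probe_conc") else probe
    eq <- fit_anisotropy_isotherm(tit$partner_total_M, tit$anisotropy, pr)
    flags <- rf$flags
    if (!eq$converged) flags <- c(flags, "isotherm_fit_failed")
    if (isTRUE(eq$poorly_determined)) flags <- c(flags,
                                                 "kd_poorly_determined")
    rows[[i]] <- cbind(meta[i, , drop = FALSE],
                       data.frame(
                         k_ass_fast = rf$k_ass_fast,
                         k_ass_fast_se = rf$k_ass_fast_se,
                         k_ass_slow = rf$k_ass_slow,
                         k_ass_slow_se = rf$k_ass_slow_se,
                         k_diss = rf$k_diss, k_diss_se = rf$k_diss_se,
                         kd_equb = eq$kd_equb, kd_equb_se = eq$kd_se,
                         flags = paste(flags, collapse = ";")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate stage: write a synthetic dataset directory
#'
#' @param out_dir output directory.
#' @param config a [run_config()] (supplies the seed).
#' @param panel_cfg a [panel_config()].
#' @param acq an [acquisition_config()].
#' @return the dataset directory, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = run_config(),
                         panel_cfg = panel_config(),
                         acq = acquisition_config()) {
  panel <- make_panel(panel_cfg)
  ds <- generate_dataset(panel, acq, seed = config$seed)
  write_dataset(ds, out_dir)
  .write_config_snapshot(config, out_dir)
  invisible(out_dir)
}

#' Fit stage: dataset directory to per-variant rate table
#'
#' @param data_dir dataset directory written by [cmd_simulate()] (or
#'   laid out identically from real experiments).
#' @param out_path output TSV path.
#' @param config a [run_config()].
#' @return the rate table, invisibly.
#' @export
cmd_fit <- function(data_dir, out_path, config = run_config()) {
  ds <- read_dataset(data_dir)
  rates <- fit_panel(ds, config)
  write_table_meta(rates, out_path,
                   meta = list(
                     rate_units = "k_ass_fast M^-1 s^-1; others s^-1",
                     kd_unit = "M",
                     convention = "SE columns are 1-sigma fit errors"))
  invisible(rates)
}

#' Phi stage: rate table to report tables
#'
#' @param rates_path rate-table TSV from [cmd_fit()], or a data.frame.
#' @param out_dir output directory for the report tables.
#' @param config a [run_config()].
#' @return the [phi_report()] object, invisibly.
#' @export
cmd_phi <- function(rates_path, out_dir, config = run_config()) {
  rates <- if (is.data.frame(rates_path)) rates_path
           else read_table_meta(rates_path)
  rep <- phi_report(rates, temperature = config$temperature,
                    ddg_threshold = config$ddg_threshold,
                    consistency_mult = config$consistency_mult,
                    class_thresholds = list(
                      unstructured = config$class_unstructured,
                      structured = config$class_structured))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conv <- paste("ddg kcal mol^-1, destabilizing positive;",
                "Phi errors assume independent inputs",
                "(shared-reference correlation ignored)")
  write_table_meta(rep$phi_table, file.path(out_dir, "phi_table.tsv"),
                   meta = list(temperature_K = config$temperature,
                               ddg_threshold = config$ddg_threshold,
                               convention = conv))
  if (!is.null(rep$region_summary))
    write_table_meta(rep$region_summary,
                     file.path(out_dir, "region_summary.tsv"),
                     meta = list(note = "reportable & consistent only"))
  lfe <- tryCatch(lfe_table(rates), error = function(e) NULL)
  if (!is.null(lfe))
    write_table_meta(lfe$table, file.path(out_dir, "lfe_table.tsv"),
                     meta = list(slope_kdiss = lfe$slope_kdiss,
                                 slope_kdiss_se = lfe$slope_kdiss_se,
                                 slope_kass = lfe$slope_kass,
                                 slope_kass_se = lfe$slope_kass_se))
  cmp <- tryCatch(compare_kd(rates), error = function(e) NULL)
  if (!is.null(cmp))
    write_table_meta(cmp$table, file.path(out_dir, "kd_comparison.tsv"),
                     meta = list(fraction_covering_one =
                                   cmp$fraction_covering_one))
  .write_config_snapshot(config, out_dir)
  invisible(rep)
}
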