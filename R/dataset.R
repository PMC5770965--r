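#' Acquisition configuration for the synthetic data generator
#'
#' Describes the simulated experiments: stopped-flow concentration series
#' and time grid, replicate count, anisotropy titration design,
#' competition series design and noise levels. Defaults are the study
#' conditions used throughout the package's own simulations.
#'
#' @param partner_concs stopped-flow partner concentrations (M).
#' @param time_grid trace time grid (s); log-spaced by default so both
#'   the fast and the slow phase are resolved.
#' @param n_replicates replicate traces per concentration.
#' @param probe_conc_trace labelled-peptide concentration in traces (M).
#' @param trace_noise_rel trace noise sd relative to the noiseless signal
#'   range.
#' @param amplitudes per-species signal coefficients for
#'   [simulate_traces()].
#' @param probe_conc_titration probe concentration in titrations (M).
#' @param n_titration_points titration points (plus one blank at L = 0).
#' @param titration_span log10 span of the titration around the design
#'   midpoint, `c(lower, upper)` decades.
#' @param anisotropy_r_free,anisotropy_r_bound free/bound anisotropies.
#' @param anisotropy_noise_sd additive anisotropy noise sd.
#' @param competitor_concs competition concentrations as multiples of
#'   `k_half`.
#' @param k_half half-saturation constant of the competition hyperbola
#'   (M).
#' @param competition_noise_rel relative (multiplicative) noise on
#'   observed displacement rates.
#' @param cd_noise_rel relative noise on generated mean residue
#'   ellipticities.
#' @param n_residues peptide length for the CD generator.
#' @param f_helix_wt wild-type residual fraction helix.
#' @param f_helix_gly_delta decrement of fraction helix for Gly variants.
#' @param f_helix_interface_delta decrement for interface Ala variants.
#' @return list of class `acquisition_config`.
#' @export
acquisition_config <- function(
    partner_concs = c(10, 15, 20, 25, 30, 40, 50, 60) * 1e-6,
    time_grid = 10^seq(log10(1e-3), log10(2), length.out = 220),
    n_replicates = 1,
    probe_conc_trace = 1e-7,
    trace_noise_rel = 0.02,
    amplitudes = c(U = 1, C = 0.8, D = 0.65),
    probe_conc_titration = 2e-9,
    n_titration_points = 11,
    titration_span = c(-1.5, 2),
    anisotropy_r_free = 0.05,
    anisotropy_r_bound = 0.25,
    anisotropy_noise_sd = 0.002,
    competitor_concs = c(0.25, 0.5, 1, 2, 4, 8, 16, 32),
    k_half = 1e-6,
    competition_noise_rel = 0.03,
    cd_noise_rel = 0.02,
    n_residues = 28,
    f_helix_wt = 0.17,
    f_helix_gly_delta = 0.03,
    f_helix_interface_delta = 0.01) {
  structure(as.list(environment()), class = "acquisition_config")
}

#' Generate per-variant mean residue ellipticities
#'
#' Inverse of [estimate_fraction_helix()]: assigns each variant a true
#' fraction helix (wild-type default 0.17; Gly variants decremented by
#' `f_helix_gly_delta`, interface Ala variants by
#' `f_helix_interface_delta`) and maps it to a noisy 222 nm mean residue
#' ellipticity under the shared baselines.
#'
#' @param panel a [make_panel()] result.
#' @param acq an [acquisition_config()].
#' @param seed integer seed; `NULL` leaves the RNG alone.
#' @return data.frame with `variant_id`, `f_helix_true`, `mre_222`.
#' @export
generate_cd <- function(panel, acq = acquisition_config(), seed = NULL) {
  stopifnot(inherits(panel, "panel_truth"))
  if (!is.null(seed)) set.seed(seed)
  v <- panel$variants
  f <- rep(acq$f_helix_wt, nrow(v))
  f[v$substitution == "to_gly"] <- acq$f_helix_wt - acq$f_helix_gly_delta
  f[v$substitution == "to_ala" & v$site_class %in% "interface"] <-
    acq$f_helix_wt - acq$f_helix_interface_delta
  mre <- mre_from_fraction_helix(f, acq$n_residues, panel$temperature)
  if (acq$cd_noise_rel > 0)
    mre <- mre * (1 + stats::rnorm(length(mre), sd = acq$cd_noise_rel))
  data.frame(variant_id = v$variant_id, f_helix_true = f, mre_222 = mre)
}

#' Generate the full synthetic dataset for a panel
#'
#' For every variant: replicate association traces over the acquisition
#' concentration series (exact scheme solution plus Gaussian noise), an
#' anisotropy titration built on the depletion-corrected bound fraction,
#' and a competition-dissociation series sampled from the saturating
#' hyperbola whose asymptote is the variant's apparent dissociation rate.
#' Variants flagged `amplitude_suppressed` produce traces without a
#' binding signal and no competition series, emulating mutations too
#' destabilizing to give a stopped-flow signal change. Fully reproducible
#' from the seed.
#'
#' @param panel a [make_panel()] result.
#' @param acq an [acquisition_config()].
#' @param seed integer seed for all noise draws.
#' @return object of class `panel_dataset`: list with `panel`, `acq`,
#'   `seed` and per-variant `traces` (list of per-concentration lists of
#'   replicate data.frames), `titrations`, `competition` (NULL when
#'   unavailable) and `cd`.
#' @export
generate_dataset <- function(panel, acq = acquisition_config(),
                             seed = 1L) {
  stopifnot(inherits(panel, "panel_truth"),
            inherits(acq, "acquisition_config"))
  set.seed(seed)
  v <- panel$variants
  traces <- titrations <- competition <- vector("list", nrow(v))
  names(traces) <- names(titrations) <- names(competition) <- v$variant_id

  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    sc <- kinetic_scheme(row$k_on, row$k_off, row$k_f, row$k_u)
    amps <- acq$amplitudes
    if (isTRUE(row$amplitude_suppressed))
      amps <- c(U = amps[["U"]], C = amps[["U"]], D = amps[["U"]])

    # noise scale from the wild-type-like dynamic range so suppressed
    # variants still carry instrument noise
    ref_tr <- simulate_traces(sc, max(acq$partner_concs),
                              acq$amplitudes, acq$time_grid,
                              noise_sd = 0)[[1]]
    nsd <- acq$trace_noise_rel * diff(range(ref_tr$signal))

    traces[[i]] <- lapply(acq$partner_concs, function(B) {
      lapply(seq_len(acq$n_replicates), function(r) {
        simulate_traces(sc, B, amps, acq$time_grid, noise_sd = nsd,
                        probe_conc = acq$probe_conc_trace)[[1]]
      })
    })
    names(traces[[i]]) <- format(acq$partner_concs, scientific = TRUE)

    # titration designed around the variant's affinity, as an
    # experimenter would after a pilot run
    mid <- max(row$kd_true, acq$probe_conc_titration / 2)
    L <- c(0, mid * 10^seq(acq$titration_span[1], acq$titration_span[2],
                           length.out = acq$n_titration_points))
    fb <- fraction_bound(L, acq$probe_conc_titration, row$kd_true)
    r <- acq$anisotropy_r_free +
      (acq$anisotropy_r_bound - acq$anisotropy_r_free) * fb
    if (acq$anisotropy_noise_sd > 0)
      r <- r + stats::rnorm(length(r), sd = acq$anisotropy_noise_sd)
    titrations[[i]] <- data.frame(partner_total_M = L, anisotropy = r)

    if (!isTRUE(row$amplitude_suppressed)) {
      cc <- acq$competitor_concs * acq$k_half
      ko <- row$kdiss_app_true * cc / (cc + acq$k_half)
      if (acq$competition_noise_rel > 0)
        ko <- ko * (1 + stats::rnorm(length(ko),
                                     sd = acq$competition_noise_rel))
      competition[[i]] <- data.frame(competitor_conc_M = cc,
                                     k_obs = ko,
                                     k_obs_se = acq$competition_noise_rel *
                                       abs(ko))
    }
  }
  cd <- generate_cd(panel, acq, seed = NULL)  # continues the seeded stream
  structure(list(panel = panel, acq = acq, seed = seed, traces = traces,
                 titrations = titrations, competition = competition,
                 cd = cd),
            class = "panel_dataset")
}

#' Serialize a synthetic dataset to delimited-text files
#'
#' Layout: `traces/<variant>_c<i>_r<j>.tsv` (columns `time_s`, `signal`;
#' header block with `variant_id` and `partner_conc_M`),
#' `titrations/<variant>.tsv`, `competition/<variant>.tsv`, `cd.tsv`,
#' `truth.tsv`, `metadata.tsv`, `config.yaml` and a checksum `manifest.tsv`.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "panel_dataset"))
  for (d in file.path(dir, c("", "traces", "titrations", "competition")))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  v <- ds$panel$variants
  for (i in seq_len(nrow(v))) {
    id <- v$variant_id[i]
    for (ci in seq_along(ds$traces[[id]])) {
      B <- ds$acq$partner_concs[ci]
      for (ri in seq_along(ds$traces[[id]][[ci]])) {
        write_table_meta(
          ds$traces[[id]][[ci]][[ri]],
          file.path(dir, "traces",
                    sprintf("%s_c%02d_r%02d.tsv", id, ci, ri)),
          meta = list(variant_id = id,
                      partner_conc_M = sprintf("%.6e", B),
                      replicate = ri,
                      time_unit = "s"))
      }
    }
    write_table_meta(ds$titrations[[id]],
                     file.path(dir, "titrations", paste0(id, ".tsv")),
                     meta = list(variant_id = id,
                                 probe_conc_M =
                                   sprintf("%.6e",
                                           ds$acq$probe_conc_titration)))
    if (!is.null(ds$competition[[id]]))
      write_table_meta(ds$competition[[id]],
                       file.path(dir, "competition", paste0(id, ".tsv")),
                       meta = list(variant_id = id, rate_unit = "s^-1"))
  }
  write_table_meta(ds$cd, file.path(dir, "cd.tsv"),
                   meta = list(mre_unit = "deg cm^2 dmol^-1 residue^-1"))
  write_table_meta(v, file.path(dir, "truth.tsv"),
                   meta = list(ddg_unit = "kcal mol^-1",
                               temperature_K = ds$panel$temperature,
                               seed = ds$seed))
  write_table_meta(
    v[, c("variant_id", "position", "region", "site_class",
          "substitution")],
    file.path(dir, "metadata.tsv"), meta = list(panel = "synthetic"))
  acq <- ds$acq
  class(acq) <- NULL
  acq$amplitudes <- as.list(acq$amplitudes)
  yaml::write_yaml(list(acquisition = acq, seed = ds$seed,
                        temperature_K = ds$panel$temperature),
                   file.path(dir, "config.yaml"))
  files <- sort(setdiff(list.files(dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(dir,
                                                              files))))
  write_table_meta(manifest, file.path(dir, "manifest.tsv"),
                   meta = list(n_files = nrow(manifest)))
  invisible(dir)
}

#' Read a serialized synthetic dataset
#'
#' @param dir directory written by [write_dataset()].
#' @return list with `truth`, `metadata`, `traces` (per variant, list of
#'   data.frames with attribute `partner_conc`), `titrations` (with
#'   attribute `probe_conc`), `competition`, `cd`.
#' @export
read_dataset <- function(dir) {
  truth <- read_table_meta(file.path(dir, "truth.tsv"))
  meta <- read_table_meta(file.path(dir, "metadata.tsv"))
  ids <- meta$variant_id
  traces <- lapply(ids, function(id) {
    fs <- sort(list.files(file.path(dir, "traces"),
                          pattern = paste0("^", id, "_c"),
                          full.names = TRUE))
    lapply(fs, function(f) {
      d <- read_table_meta(f)
      attr(d, "partner_conc") <- as.numeric(attr(d, "meta")$partner_conc_M)
      d
    })
  })
  names(traces) <- ids
  titrations <- lapply(ids, function(id) {
    d <- read_table_meta(file.path(dir, "titrations",
                                   paste0(id, ".tsv")))
    attr(d, "probe_conc") <- as.numeric(attr(d, "meta")$probe_conc_M)
    d
  })
  names(titrations) <- ids
  competition <- lapply(ids, function(id) {
    f <- file.path(dir, "competition", paste0(id, ".tsv"))
    if (file.exists(f)) read_table_meta(f) else NULL
  })
  names(competition) <- ids
  list(truth = truth, metadata = meta, traces = traces,
       titrations = titrations, competition = competition,
       cd = read_table_meta(file.path(dir, "cd.tsv")))
}
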