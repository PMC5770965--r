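biexp_trace <- function(rates = c(11.794362, 4.705638),
                        amps = c(0.061, 0.273), offset = 0.667,
                        times = 10^seq(-3, log10(2), length.out = 220),
                        noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- offset + amps[1] * exp(-rates[1] * times) +
    amps[2] * exp(-rates[2] * times)
  if (noise_sd > 0) y <- y + rnorm(length(y), sd = noise_sd)
  data.frame(time_s = times, signal = y)
}

test_that("noiseless biexponential fits recover both rates to 0.1%", {
  f <- fit_exponential(biexp_trace(), 2)
  expect_true(f$converged)
  expect_false(f$degenerate)
  expect_equal(f$rates, c(11.794362, 4.705638), tolerance = 1e-3)
  expect_equal(f$offset, 0.667, tolerance = 1e-4)
})

test_that("pure-offset traces give near-zero amplitudes and a degenerate flag", {
  tr <- biexp_trace(amps = c(0, 0))
  f <- fit_exponential(tr, 2)
  expect_true(all(abs(f$amplitudes) < 1e-8, na.rm = TRUE) || f$degenerate)
  expect_true(f$degenerate)
})

test_that("fitted fast rates cover the truth under 2% noise", {
  # well-separated phases (ratio 8), the regime the study design keeps
  # the concentration series in
  hits <- 0L
  for (s in 1:50) {
    tr <- biexp_trace(rates = c(40, 5), amps = c(0.2, 0.12),
                      noise_sd = 0.02 * 0.32, seed = s)
    f <- fit_exponential(tr, 2)
    if (f$converged && !f$degenerate &&
        abs(f$rates[1] - 40) <= 3 * f$rate_se[1])
      hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})

test_that("phase selection prefers the true model", {
  # single-exponential truth: one phase chosen
  tr1 <- biexp_trace(amps = c(0, 0.3), noise_sd = 0.006, seed = 1)
  expect_identical(choose_phases(fit_exponential(tr1, 1),
                                 fit_exponential(tr1, 2)), 1L)
  # well-separated biphasic truth with >= 20% slow amplitude: two phases
  n2 <- 0L
  for (s in 1:30) {
    tr <- biexp_trace(rates = c(20, 5), amps = c(0.25, 0.09),
                      noise_sd = 0.006, seed = s)
    n2 <- n2 + (choose_phases(fit_exponential(tr, 1),
                              fit_exponential(tr, 2)) == 2L)
  }
  expect_gte(n2 / 30, 0.95)
  # slow amplitude far below the noise floor: resolvability lost
  trs <- biexp_trace(rates = c(20, 5), amps = c(0.3, 3e-4),
                     noise_sd = 0.006, seed = 7)
  expect_identical(choose_phases(fit_exponential(trs, 1),
                                 fit_exponential(trs, 2)), 1L)
})

test_that("false biphasic selection is rare on single-exponential traces", {
  n2 <- 0L
  for (s in 1:200) {
    tr <- biexp_trace(amps = c(0, 0.3), noise_sd = 0.006, seed = s)
    n2 <- n2 + (choose_phases(fit_exponential(tr, 1),
                              fit_exponential(tr, 2)) == 2L)
  }
  expect_lt(n2 / 200, 0.05)
})

test_that("association series on exact two-state rates is machine precise", {
  sc <- kinetic_scheme(4e6, 0.2)
  B <- c(1, 2, 3, 4, 5) * 1e-5
  er <- eigen_rates(sc, B)
  fit <- fit_association_series(B, er$lambda_fast)
  expect_equal(fit$k_ass_fast, sc$k_on, tolerance = 1e-10)
  expect_equal(fit$intercept, sc$k_off, tolerance = 1e-8)
})

test_that("association slope on the three-state scheme recovers k_on within 5%", {
  sc <- kinetic_scheme(1e6, 1, 5, 0.5)
  B <- seq(5, 50, length.out = 8) * 1e-6
  er <- eigen_rates(sc, B)
  fit <- fit_association_series(B, er$lambda_fast)
  expect_lt(abs(fit$k_ass_fast - sc$k_on) / sc$k_on, 0.05)
})

test_that("duplicate concentrations leave the regression well posed", {
  B <- c(1, 1, 2, 2, 3, 3) * 1e-5
  lam <- 2e6 * B + 0.5
  fit <- fit_association_series(B, lam)
  expect_equal(fit$k_ass_fast, 2e6, tolerance = 1e-10)
  expect_error(fit_association_series(B, rev(seq_along(B))),
               "not positive")
  expect_error(fit_association_series(B[1:3], lam[1:3]), "at least 4")
})

test_that("slow-phase summary flags concentration independence", {
  B <- seq(5, 50, length.out = 8) * 1e-6
  s <- summarize_slow_phase(B, rep(4.7, 8))
  expect_equal(s$k_ass_slow, 4.7)
  expect_identical(s$k_ass_slow_se, 0)
  sc <- kinetic_scheme(1e6, 1, 5, 0.5)
  er <- eigen_rates(sc, B)
  s2 <- summarize_slow_phase(B, er$lambda_slow)
  expect_gte(s2$k_ass_slow, 4.2)
  expect_lte(s2$k_ass_slow, sc$k_f + sc$k_u)
})

test_that("slow rates stay within 1.5-fold across a shared-isomerization panel", {
  panel <- make_panel()
  v <- panel$variants
  v <- v[!v$amplitude_suppressed, ]
  B <- acquisition_config()$partner_concs
  means <- vapply(seq_len(nrow(v)), function(i) {
    sc <- kinetic_scheme(v$k_on[i], v$k_off[i], v$k_f[i], v$k_u[i])
    mean(eigen_rates(sc, B)$lambda_slow)
  }, 0)
  wt <- means[v$substitution == "wild_type"]
  expect_true(all(means / wt < 1.5 & means / wt > 1 / 1.5))
})

test_that("dissociation asymptote round trips and flags saturation", {
  cc <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32) * 1e-6
  ko <- 0.078 * cc / (cc + 1e-6)
  fit <- fit_dissociation_asymptote(cc, ko)
  expect_equal(fit$k_diss, 0.078, tolerance = 1e-3)
  expect_equal(fit$k_half, 1e-6, tolerance = 1e-3)

  sat <- fit_dissociation_asymptote(cc, rep(0.078, 8))
  expect_true(sat$saturated)
  expect_equal(sat$k_diss, 0.078)
  expect_true(is.na(sat$k_half))

  expect_error(fit_dissociation_asymptote(cc, rev(seq_along(cc)) / 100),
               "model mismatch")
  expect_warning(fit_dissociation_asymptote(cc[1:5], ko[1:5]),
                 "plateaued")
})

test_that("noisy asymptote estimates are unbiased within Monte-Carlo error", {
  cc <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32) * 1e-6
  mu <- 0.078 * cc / (cc + 1e-6)
  est <- vapply(1:60, function(s) {
    set.seed(s)
    ko <- mu * (1 + rnorm(8, sd = 0.05))
    suppressWarnings(
      fit_dissociation_asymptote(cc, ko, k_obs_se = 0.05 * mu)$k_diss)
  }, 0)
  bias <- mean(est) - 0.078
  expect_lt(abs(bias), 3 * sd(est) / sqrt(60))
})

test_that("rate SEs shrink roughly as 1/sqrt(replicates)", {
  sc <- kinetic_scheme(1e6, 1, 5, 0.5)
  tg <- 10^seq(-3, log10(2), length.out = 220)
  amps <- c(U = 1, C = 0.8, D = 0.65)
  se_for <- function(n_rep, seed) {
    trs <- simulate_traces(sc, rep(1e-5, n_rep), amps, tg,
                           noise_sd = 0.02 * 0.33, seed = seed)
    avg <- trs[[1]]
    avg$signal <- rowMeans(vapply(trs, function(d) d$signal,
                                  numeric(nrow(avg))))
    fit_exponential(avg, 2)$rate_se[1]
  }
  se1 <- median(vapply(1:8, function(s) se_for(1, s), 0))
  se4 <- median(vapply(1:8, function(s) se_for(4, 100 + s), 0))
  se16 <- median(vapply(1:8, function(s) se_for(16, 200 + s), 0))
  expect_equal(se1 / se4, 2, tolerance = 0.4)
  expect_equal(se4 / se16, 2, tolerance = 0.4)
})

test_that("simulate -> fit -> series round trip recovers k_on", {
  sc <- kinetic_scheme(4e6, 0.02, 4, 1)
  acq <- acq_noiseless()
  # noiseless: within 0.5%
  lams <- vapply(acq$partner_concs, function(B) {
    tr <- simulate_traces(sc, B, acq$amplitudes, acq$time_grid)[[1]]
    fit_exponential(tr, 2)$rates[1]
  }, 0)
  fit <- fit_association_series(acq$partner_concs, lams)
  expect_lt(abs(fit$k_ass_fast - sc$k_on) / sc$k_on, 0.005)
  # 2% noise: within 2 SE at most seeds
  hits <- 0L
  for (s in 1:15) {
    res <- vapply(acq$partner_concs, function(B) {
      tr <- simulate_traces(sc, B, acq$amplitudes, acq$time_grid,
                            noise_sd = 0.02 * 0.35, seed = s * 1000 + B * 1e6)[[1]]
      f <- fit_exponential(tr, 2)
      c(f$rates[1], f$rate_se[1])
    }, c(0, 0))
    fitn <- fit_association_series(acq$partner_concs, res[1, ], res[2, ])
    if (abs(fitn$k_ass_fast - sc$k_on) <= 2.5 * fitn$k_ass_fast_se)
      hits <- hits + 1L
  }
  expect_gte(hits / 15, 0.8)
})
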