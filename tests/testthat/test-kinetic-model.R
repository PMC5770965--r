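test_that("closed-form relaxation rates match the worked three-state scheme", {
  sc <- kinetic_scheme(k_on = 1e6, k_off = 1, k_f = 5, k_u = 0.5)
  er <- eigen_rates(sc, 1e-5)
  # frozen from the numerical eigen-decomposition of the 2x2 rate matrix
  expect_equal(er$lambda_fast, 11.794362, tolerance = 1e-6)
  expect_equal(er$lambda_slow, 4.705638, tolerance = 1e-6)
  expect_equal(unlist(er[, c("lambda_fast", "lambda_slow")],
                      use.names = FALSE),
               eigen_rates_oracle(sc, 1e-5), tolerance = 1e-9)
})

test_that("two-state limit and zero-concentration cases are exact", {
  sc <- kinetic_scheme(k_on = 1e6, k_off = 1)
  er <- eigen_rates(sc, 1e-5)
  expect_identical(er$lambda_slow, 0)
  expect_equal(er$lambda_fast, 1e6 * 1e-5 + 1, tolerance = 1e-12)

  sc3 <- kinetic_scheme(1e6, 1, 5, 0.5)
  er0 <- eigen_rates(sc3, 0)
  expect_equal(c(er0$lambda_fast, er0$lambda_slow),
               eigen_rates_oracle(sc3, 0), tolerance = 1e-9)
})

test_that("trace and determinant identities hold at machine precision", {
  set.seed(101)
  for (i in 1:25) {
    sc <- random_scheme()
    B <- 10^stats::runif(1, -7, -4)
    er <- eigen_rates(sc, B)
    M <- rate_matrix(sc, B)
    expect_equal(er$lambda_fast + er$lambda_slow, -sum(diag(M)),
                 tolerance = 1e-12)
    expect_equal(er$lambda_fast * er$lambda_slow, det(M),
                 tolerance = 1e-9)
  }
})

test_that("fast phase is asymptotically linear with slope k_on", {
  sc <- kinetic_scheme(k_on = 4e6, k_off = 0.02, k_f = 4, k_u = 1)
  B <- seq(1, 10, length.out = 10) * 10 * sc$k_off / sc$k_on * 1e3
  er <- eigen_rates(sc, B)
  slope <- diff(range(er$lambda_fast)) / diff(range(B))
  expect_lt(abs(slope - sc$k_on) / sc$k_on, 0.05)
})

test_that("slow phase is bounded by k_f + k_u for any concentration", {
  set.seed(202)
  for (i in 1:20) {
    sc <- random_scheme()
    er <- eigen_rates(sc, 10^seq(-8, -3, length.out = 30))
    expect_true(all(er$lambda_slow <= sc$k_f + sc$k_u + 1e-9))
  }
})

test_that("equilibrium Kd follows detailed balance over both bound states", {
  sc <- kinetic_scheme(1e6, 1, 5, 0.5)
  expect_equal(equilibrium_kd(sc), 1e-6 / 11, tolerance = 1e-12)
  # symmetric isomerization halves the two-state Kd
  sym <- kinetic_scheme(1e6, 1, 2, 2)
  expect_equal(equilibrium_kd(sym), 1 / (2 * 1e6), tolerance = 1e-12)
  expect_equal(equilibrium_kd(kinetic_scheme(1e6, 1)), 1e-6,
               tolerance = 1e-15)
  expect_error(equilibrium_kd(kinetic_scheme(1e6, 1, k_f = 2, k_u = 0)),
               "infinite affinity")
})

test_that("apparent k_off matches the competitor-trap eigenvalue", {
  sc <- kinetic_scheme(1e6, 1, 5, 0.5)
  expect_equal(apparent_koff(sc), 0.07785561, tolerance = 1e-6)
  expect_equal(apparent_koff(sc), apparent_koff_oracle(sc),
               tolerance = 1e-9)
  expect_identical(apparent_koff(kinetic_scheme(1e6, 1)), 1)
  # kinetic and equilibrium Kd differ for the three-state scheme and the
  # package exposes both
  expect_equal(kinetic_kd_scheme(sc), 7.785561e-8, tolerance = 1e-6)
  expect_equal(equilibrium_kd(sc), 9.090909e-8, tolerance = 1e-6)
})

test_that("two-state kinetic and equilibrium Kd are identical", {
  set.seed(303)
  for (i in 1:10) {
    sc <- kinetic_scheme(10^stats::runif(1, 5, 8),
                         10^stats::runif(1, -2, 2))
    expect_identical(equilibrium_kd(sc), apparent_koff(sc) / sc$k_on)
  }
})

test_that("scheme validation rejects non-positive core rates", {
  expect_error(kinetic_scheme(0, 1), "strictly positive")
  expect_error(kinetic_scheme(1e6, -1), "strictly positive")
  expect_error(kinetic_scheme(1e6, 1, -1, 2), "non-negative")
  expect_error(eigen_rates(kinetic_scheme(1e6, 1), -1e-6), ">= 0")
})

test_that("noiseless traces match independent ODE integration", {
  skip_if_not_installed("deSolve")
  times <- 10^seq(-3, log10(2), length.out = 80)
  set.seed(404)
  for (i in 1:5) {
    sc <- random_scheme()
    B <- 2e-5
    X <- species_fractions(sc, B, times)
    O <- ode_fractions(sc, B, times)
    expect_equal(X[, "C"], unname(O[, "C"]), tolerance = 1e-6)
    expect_equal(X[, "D"], unname(O[, "D"]), tolerance = 1e-6)
  }
})

test_that("trace simulation is seed-deterministic and validates inputs", {
  sc <- kinetic_scheme(1e6, 1, 5, 0.5)
  tg <- seq(0.001, 1, length.out = 50)
  amps <- c(U = 1, C = 0.8, D = 0.6)
  a <- simulate_traces(sc, c(1e-5, 2e-5), amps, tg, noise_sd = 0.01,
                       seed = 99)
  b <- simulate_traces(sc, c(1e-5, 2e-5), amps, tg, noise_sd = 0.01,
                       seed = 99)
  expect_identical(a, b)
  expect_error(simulate_traces(sc, numeric(0), amps, tg), "at least one")
  expect_error(simulate_traces(sc, 1e-5, amps, tg, noise_sd = -1), ">= 0")
  expect_error(simulate_traces(sc, 1e-5, amps, rev(tg)), "increasing")
  expect_warning(simulate_traces(sc, 5e-7, amps, tg, probe_conc = 1e-7),
                 "pseudo-first-order")
})

test_that("dissociation-mode traces start from the equilibrium bound ratio", {
  sc <- kinetic_scheme(1e6, 1, 5, 0.5)
  X <- species_fractions(sc, 0, c(1e-6, 20, 30), mode = "dissociation")
  expect_equal(unname(X[1, "D"] / X[1, "C"]), sc$k_f / sc$k_u,
               tolerance = 1e-4)
  # late-time decay rate of total bound equals the apparent k_off
  b <- rowSums(X)
  lam <- log(b[2] / b[3]) / 10
  expect_equal(lam, apparent_koff(sc), tolerance = 1e-6)
})
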