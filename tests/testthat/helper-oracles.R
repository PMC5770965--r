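# Independent numerical oracles used across the suite. These never call
# the closed-form implementations they are checking.

# random scheme with log-uniform rates in physically sensible decades
random_scheme <- function() {
  kinetic_scheme(k_on = 10^stats::runif(1, 5, 8),
                 k_off = 10^stats::runif(1, -2, 2),
                 k_f = 10^stats::runif(1, -2, 2),
                 k_u = 10^stats::runif(1, -2, 2))
}

# relaxation rates by numerical eigen-decomposition of the (C, D) system
eigen_rates_oracle <- function(scheme, B) {
  kb <- scheme$k_on * B
  M <- matrix(c(-(kb + scheme$k_off + scheme$k_f), scheme$k_f,
                scheme$k_u - kb, -scheme$k_u), 2, 2)
  sort(-Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
}

# competitor-trap slow rate by numerical eigen-decomposition
apparent_koff_oracle <- function(scheme) {
  M <- matrix(c(-(scheme$k_off + scheme$k_f), scheme$k_f,
                scheme$k_u, -scheme$k_u), 2, 2)
  min(-Re(eigen(M, only.values = TRUE)$values))
}

# overall Kd from the stationary distribution of the full 3-species
# generator at fixed free partner concentration B
equilibrium_kd_oracle <- function(scheme, B = 1e-6) {
  G <- matrix(c(-scheme$k_on * B, scheme$k_on * B, 0,
                scheme$k_off, -(scheme$k_off + scheme$k_f), scheme$k_f,
                0, scheme$k_u, -scheme$k_u),
              3, 3)  # columns: from-state U, C, D
  ns <- eigen(G)
  v <- Re(ns$vectors[, which.min(abs(Re(ns$values)))])
  v <- v / sum(v)
  B * v[1] / (v[2] + v[3])
}

# full 3-species ODE integration (association from all-unbound)
ode_fractions <- function(scheme, B, times) {
  f <- function(t, y, p) {
    U <- y[1]; C <- y[2]; D <- y[3]
    list(c(-scheme$k_on * B * U + scheme$k_off * C,
           scheme$k_on * B * U - (scheme$k_off + scheme$k_f) * C +
             scheme$k_u * D,
           scheme$k_f * C - scheme$k_u * D))
  }
  out <- deSolve::lsoda(c(U = 1, C = 0, D = 0), c(0, times), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
  out[-1, c("C", "D"), drop = FALSE]
}

# Monte-Carlo propagation of a scalar function of independent Gaussian
# inputs: returns the sd of the sampled outputs
mc_se <- function(fn, means, sds, n = 1e5, seed = 42) {
  set.seed(seed)
  draws <- mapply(function(m, s) stats::rnorm(n, m, s), means, sds)
  stats::sd(apply(draws, 1, function(x) do.call(fn, as.list(x))))
}

# small zero-noise acquisition used by several tests
acq_noiseless <- function(...) {
  acquisition_config(trace_noise_rel = 0, anisotropy_noise_sd = 0,
                     competition_noise_rel = 0, cd_noise_rel = 0, ...)
}
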