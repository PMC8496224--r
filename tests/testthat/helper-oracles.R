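# Independent oracles and shared fixtures. Everything here is deliberately
# brute-force / closed-form and does not reuse the solver or kernel code
# paths it checks.

# fixed-step classical RK4 for y' = f(t, y); high-accuracy ODE reference
rk4_reference <- function(f, y0, tmax, n_steps = 20000L) {
  h <- tmax / n_steps
  y <- y0
  t <- 0
  for (k in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    t <- t + h
  }
  y
}

# dense RK4 reference: returns states at the requested times
rk4_reference_path <- function(f, y0, times, substeps = 50L) {
  out <- matrix(0, length(times), length(y0))
  out[1L, ] <- y0
  y <- y0
  for (i in seq_len(length(times) - 1L)) {
    h <- (times[i + 1L] - times[i]) / substeps
    t <- times[i]
    for (k in seq_len(substeps)) {
      k1 <- f(t, y)
      k2 <- f(t + h / 2, y + h / 2 * k1)
      k3 <- f(t + h / 2, y + h / 2 * k2)
      k4 <- f(t + h, y + h * k3)
      y <- y + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
      t <- t + h
    }
    out[i + 1L, ] <- y
  }
  out
}

# inverse-CDF sampler for the discrete power law P(k) = k^-alpha / Z on
# k = 1..kmax (kmax chosen so truncation mass is negligible)
sample_discrete_powerlaw <- function(n, alpha, kmax = 100000L) {
  pk <- (1:kmax)^(-alpha)
  pk <- pk / sum(pk)
  sample.int(kmax, n, replace = TRUE, prob = pk)
}

# variance of a Normal(mu, sigma^2) truncated below at a (resampling scheme)
truncnorm_lower_variance <- function(mu, sigma, a) {
  al <- (a - mu) / sigma
  lam <- stats::dnorm(al) / (1 - stats::pnorm(al))
  sigma^2 * (1 + al * lam - lam^2)
}

# small fixed test network: 5 genes, gene 1 -> activates 2, 3 -> represses 2,
# 4 -> activates 5
fixture_net5 <- function() {
  A <- matrix(0, 5, 5); R <- matrix(0, 5, 5)
  A[1, 2] <- 1; A[4, 5] <- 1
  R[3, 2] <- 1
  regulatory_network(A, R, core_genes = c(2L, 5L))
}

fixture_params5 <- function(Tmax = 60) {
  list(reg = regulatory_params(5),
       kin = kinetic_params(5, Kx = 2, Ks = 1, Zx = 0.2, Zs = 0.2,
                            Tmax = Tmax))
}

# deterministic scaled-down study world shared by the G-by-G / G-by-E
# acceptance tests: 50 genes, 12 core, 200 individuals, shortened Tmax
# (dynamics relax within ~100 min at Zx = Zs = 0.05, so averaging over
# [40, 200] is past the transient)
fixture_study <- function(seed = 42L) {
  net <- generate_network(50L, n_core = 12L, seed = seed)
  pop <- simulate_genotypes(200L, 50L, seed = seed + 1L)
  list(net = net, pop = pop,
       reg = regulatory_params(50L),
       kin = kinetic_params(50L, Tmax = 200))
}
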