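# Thermodynamic kernel and numerical integration.

test_that("masked concentrations select exactly the regulators", {
  net <- fixture_net5()
  s <- c(3, 5, 7, 11, 13)
  expect_equal(masked_concentrations(s, net$A, 2L), c(3, 0, 0, 0, 0))
  expect_equal(masked_concentrations(s, net$R, 2L), c(0, 0, 7, 0, 0))
  expect_equal(masked_concentrations(s, net$A, 1L), rep(0, 5))
  expect_error(masked_concentrations(s[1:3], net$A, 2L), "mismatch")
})

test_that("activator and repressor factors match hand substitutions", {
  reg1 <- regulatory_params(1, GA = 0, GR = 0, Phi = 2, hA = 1, hR = 1,
                            exponent_base = 1)
  expect_equal(activator_factor(1, reg1), 1.5)  # (1 + 2)/(1 + 1)
  expect_equal(repressor_factor(1, reg1), 0.5)  # 1/(1 + 1)

  reg <- regulatory_params(5)
  expect_equal(activator_factor(rep(0, 5), reg), rep(1, 5))
  expect_equal(repressor_factor(rep(0, 5), reg), rep(1, 5))
  regPhi1 <- regulatory_params(5, Phi = 1)
  expect_equal(activator_factor(c(0, 1, 4, 9, 100), regPhi1), rep(1, 5))

  # strict monotone decrease of the repressor factor along a grid
  grid <- c(0, 1, 2, 4, 8)
  vals <- vapply(grid, function(s) repressor_factor(s, reg1), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("regulatory factor equals the dense determinant oracle", {
  expect_equal(regulatory_factor(rep(1, 4), rep(1, 4)), 1)
  expect_equal(regulatory_factor(c(1.5, 1, 1), c(1, 0.5, 1)), 0.75)
  set.seed(12)
  for (n in c(3L, 8L)) {
    fA <- runif(n, 0.5, 2); fR <- runif(n, 0.1, 1)
    oracle <- det(diag(fA, n) %*% diag(fR, n))
    expect_equal(regulatory_factor(fA, fR), oracle)
  }
})

test_that("binding probability: substitutions, limits and both forms", {
  reg <- regulatory_params(1, Gp = 0, H = 1, exponent_base = 1)
  expect_equal(binding_probability(1, reg), 1)  # raw 2/(1+1), clamped top
  regBig <- regulatory_params(1, Gp = 50, H = 1)
  expect_lt(binding_probability(1, regBig), 1e-20)
  # F = exp(Gp/H) makes the raw occupancy value exactly 1
  reg2 <- regulatory_params(1, Gp = 1.3, H = 1)
  expect_equal(binding_probability(exp(1.3), reg2), 1)
  expect_error(regulatory_params(1, H = -1), "positive")

  # literal reading decreases in F; occupancy increases
  lit <- regulatory_params(1, Gp = 1, H = 1, binding_form = "literal")
  occ <- regulatory_params(1, Gp = 1, H = 1)
  Fs <- c(0.5, 1, 2, 4)
  pl <- vapply(Fs, binding_probability, numeric(1), reg = lit)
  po <- vapply(Fs, binding_probability, numeric(1), reg = occ)
  expect_true(all(diff(pl) < 0))
  expect_true(all(diff(po) > 0))
})

test_that("p stays in [0,1] and responds monotonically to regulators", {
  net <- fixture_net5()
  reg <- regulatory_params(5)
  set.seed(3)
  for (k in 1:20) {
    s <- runif(5, 0, 50)
    p <- binding_probabilities(s, reg, net)
    expect_true(all(p >= 0 & p <= 1))
  }
  # gene 2 is activated by 1 and repressed by 3
  p_of <- function(s1, s3) binding_probabilities(c(s1, 0, s3, 0, 0),
                                                 reg, net)[2L]
  act_grid <- vapply(seq(0, 20, by = 2), p_of, numeric(1), s3 = 1)
  expect_true(all(diff(act_grid) >= 0))
  rep_grid <- vapply(seq(0, 20, by = 2), function(s3) p_of(1, s3), numeric(1))
  expect_true(all(diff(rep_grid) <= 0))
})

test_that("rhs vanishes at the frozen-p analytic fixed point", {
  net <- fixture_net5()
  reg <- regulatory_params(5)
  set.seed(8)
  for (k in 1:10) {
    kin <- kinetic_params(5, Kx = runif(5, 0.5, 4), Ks = runif(5, 0.5, 4),
                          Zx = runif(5, 0.05, 1), Zs = runif(5, 0.05, 1))
    s_star_guess <- runif(5, 0, 10)
    p_bar <- binding_probabilities(s_star_guess, reg, net)
    x_star <- kin$Kx * p_bar / kin$Zx
    s_star <- kin$Ks * x_star / kin$Zs
    d <- regulatory_rhs(x_star, s_star, x_star, s_star_guess, kin, reg, net)
    expect_equal(d$dx, rep(0, 5), tolerance = 1e-12)
    expect_equal(max(abs(kin$Ks * x_star - kin$Zs * s_star)), 0,
                 tolerance = 1e-12)
  }
  # zero state, unregulated genes, Gp = 0: dx = Kx, ds = 0
  empty <- regulatory_network(matrix(0, 3, 3), matrix(0, 3, 3))
  reg0 <- regulatory_params(3, Gp = 0)
  kin3 <- kinetic_params(3, Kx = 2)
  d0 <- regulatory_rhs(rep(0, 3), rep(0, 3), rep(0, 3), rep(0, 3),
                       kin3, reg0, empty)
  expect_equal(d0$dx, rep(2, 3))  # p = 2/(1+1) = 1
  expect_equal(d0$ds, rep(0, 3))
  # explicit arithmetic fixed point: Kx=2, p=0.5, Zx=1 -> x*=1; Ks=3, Zs=1.5 -> s*=2
  reg_half <- regulatory_params(1, Gp = log(3), H = 1)
  kin1 <- kinetic_params(1, Kx = 2, Ks = 3, Zx = 1, Zs = 1.5)
  e1 <- regulatory_network(matrix(0, 1, 1), matrix(0, 1, 1))
  d1 <- regulatory_rhs(1, 2, 1, 2, kin1, reg_half, e1)
  expect_equal(c(d1$dx, d1$ds), c(0, 0))
})

test_that("Euler-Maruyama: step rule, determinism, gamma=0 accuracy", {
  net <- fixture_net5()
  prm <- fixture_params5(Tmax = 60)
  init <- rep(1, 10)

  em <- integrate_em(init, prm$kin, prm$reg, net, seed = 1)
  expect_length(em$times, 2001L)  # dt = 5e-4 * Tmax for any Tmax
  expect_equal(max(em$times), 60)

  noisy_kin <- kinetic_params(5, Kx = 2, Ks = 1, Zx = 0.2, Zs = 0.2,
                              Tmax = 60, gamma = 0.05, sigma_q = 0.2)
  a <- integrate_em(init, noisy_kin, prm$reg, net, seed = 7)
  b <- integrate_em(init, noisy_kin, prm$reg, net, seed = 7)
  c2 <- integrate_em(init, noisy_kin, prm$reg, net, seed = 8)
  expect_identical(a$x, b$x)
  expect_false(identical(a$x, c2$x))
  expect_true(all(a$x >= 0) && all(a$s >= 0))

  # gamma = 0 tracks an independent fixed-step RK4 reference at the
  # first-order accuracy the fixed 2000-step rule permits (~dt/2 * |y''|,
  # a few 1e-3 relative here)
  f <- function(t, y) {
    d <- regulatory_rhs(y[1:5], y[6:10], y[1:5], y[6:10],
                        prm$kin, prm$reg, net)
    c(d$dx, d$ds)
  }
  ref <- rk4_reference_path(f, init, em$times, substeps = 2L)
  rel_err <- max(abs(cbind(em$x, em$s) - ref) / pmax(abs(ref), 1))
  expect_lt(rel_err, 1e-2)
})

test_that("delay solver reproduces the method-of-steps closed form", {
  sol <- rk23_solve(function(t, y, ylag) -ylag, 1, tau = 1, tmax = 2,
                    rel_tol = 1e-6, abs_tol = 1e-9)
  at <- function(tt) approx(sol$times, sol$states[, 1], xout = tt)$y
  expect_lt(abs(at(1) - 0), 1e-4)       # y(1) = 0
  expect_lt(abs(at(2) - (-0.5)), 1e-4)  # y(2) = -1/2
})

test_that("RK23 at tau=0 matches the RK4 reference and converges", {
  net <- fixture_net5()
  prm <- fixture_params5(Tmax = 60)
  init <- rep(1, 10)
  f <- function(t, y) {
    d <- regulatory_rhs(y[1:5], y[6:10], y[1:5], y[6:10],
                        prm$kin, prm$reg, net)
    c(d$dx, d$ds)
  }
  y_ref <- rk4_reference(f, init, 60, n_steps = 20000L)

  end_state <- function(rel, abs) {
    tr <- integrate_dde(init, prm$kin, prm$reg, net, rel_tol = rel,
                        abs_tol = abs)
    c(tr$x[nrow(tr$x), ], tr$s[nrow(tr$s), ])
  }
  err1 <- max(abs(end_state(1e-3, 1e-6) - y_ref))
  expect_lt(err1, 1e-3 * max(abs(y_ref)))
  # halving tolerances does not increase the error
  err2 <- max(abs(end_state(5e-4, 5e-7) - y_ref))
  expect_lte(err2, err1 + 1e-12)
})

test_that("EM (gamma=0) and RK23 (tau=0) agree on a shared system", {
  net <- fixture_net5()
  prm <- fixture_params5(Tmax = 60)
  init <- rep(1, 10)
  em <- integrate_em(init, prm$kin, prm$reg, net, seed = 1)
  rk <- integrate_dde(init, prm$kin, prm$reg, net, rel_tol = 1e-6,
                      abs_tol = 1e-9)
  rk_end <- c(rk$x[nrow(rk$x), ], rk$s[nrow(rk$s), ])
  em_end <- c(em$x[nrow(em$x), ], em$s[nrow(em$s), ])
  expect_lt(max(abs(rk_end - em_end) / pmax(abs(rk_end), 1)), 1e-2)
})

test_that("delayed and stochastic mechanisms are mutually exclusive", {
  expect_error(kinetic_params(5, tau = 1, gamma = 0.1), "tau = 0")
  net <- fixture_net5()
  kin_tau <- kinetic_params(5, tau = 1, Tmax = 10)
  expect_error(integrate_em(rep(1, 10), kin_tau, regulatory_params(5), net),
               "tau = 0")
})

test_that("unregulated genes relax along the scalar closed form", {
  e1 <- regulatory_network(matrix(0, 1, 1), matrix(0, 1, 1))
  reg <- regulatory_params(1)  # baseline p = 0.5
  kin <- kinetic_params(1, Kx = 2, Ks = 1, Zx = 0.2, Zs = 0.1, Tmax = 80)
  tr <- integrate_dde(rep(1, 2), kin, reg, e1, rel_tol = 1e-6, abs_tol = 1e-9)
  p_hat <- 0.5
  closed <- 1 * exp(-0.2 * tr$times) + (2 * p_hat / 0.2) *
    (1 - exp(-0.2 * tr$times))
  expect_lt(max(abs(tr$x[, 1] - closed)), 1e-3 * max(closed))

  # simulate_genotype averages converge to Kx p / Zx for Tmax >> 1/Zx
  gp <- simulate_genotype(2, kin, reg, e1, mode = "deterministic",
                          genotype_id = "g1")
  expect_lt(abs(gp$mean_mrna[1] - 5) / 5, 0.02)
})

test_that("simulate_genotype: window, determinism, delay mode", {
  net <- fixture_net5()
  prm <- fixture_params5(Tmax = 60)
  Kx <- rep(2, 5)
  g1 <- simulate_genotype(Kx, prm$kin, prm$reg, net, mode = "deterministic")
  g2 <- simulate_genotype(Kx, prm$kin, prm$reg, net, mode = "deterministic")
  expect_identical(g1$mean_protein, g2$mean_protein)

  # averaging window starts at burn_in * Tmax: constant-1 head cannot
  # contaminate a window average computed from t >= 12
  avg_all <- time_average(g1$trajectory, 0)
  avg_win <- time_average(g1$trajectory, 0.2)
  expect_false(isTRUE(all.equal(avg_all$mean_mrna, avg_win$mean_mrna)))

  kin_tau <- kinetic_params(5, Kx = 2, Ks = 1, Zx = 0.2, Zs = 0.2,
                            tau = 2, Tmax = 60)
  gd <- simulate_genotype(Kx, kin_tau, prm$reg, net, mode = "delay")
  expect_identical(gd$trajectory$mode, "delay")
  expect_true(all(gd$mean_protein >= 0))
  expect_error(simulate_genotype(Kx, prm$kin, prm$reg, net, mode = "delay",
                                 genotype_id = "gX"), "gX")
})
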