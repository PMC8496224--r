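# Thermodynamic transcription kernel and numerical integration of the
# coupled mRNA/protein dynamics.
#
# Per gene i the mRNA production rate is Kx_i * p_i, where p_i is the
# promoter-binding probability of RNA polymerase II. p_i depends on the
# concentrations of gene i's regulators through activator/repressor factors
# derived from a statistical-thermodynamic occupancy model; protein
# production is linear in mRNA.

#' Regulatory (thermodynamic) parameters
#'
#' Scalar arguments are broadcast to length \code{n}.
#'
#' @param n Number of genes.
#' @param Gp Relative free energies of RNAP II promoter binding
#'   (dimensionless, in units of the binding constant H). The default
#'   \code{log(3)} with \code{H = 1} gives a baseline binding probability of
#'   0.5 for an unregulated gene.
#' @param H Positive RNAP II binding constants.
#' @param GA,GR Relative free energies of activator / repressor binding.
#' @param Phi Activator binding interaction constants; activation requires
#'   \code{Phi > 1}.
#' @param hA,hR Positive activator / repressor constants.
#' @param exponent_base The "n" of the 1/n exponents in the regulatory
#'   factors; defaults to the gene count, with
#'   \code{exponent_mode = "regulators"} available to use each gene's
#'   regulator count instead.
#' @param exponent_mode \code{"genes"} (default) or \code{"regulators"}.
#' @param binding_form \code{"occupancy"} (default): \eqn{p_i = 2 / (1 +
#'   F_i^{-1} e^{G_{p,i}/H_i})}, increasing in the regulatory factor
#'   \eqn{F_i}; or \code{"literal"}: \eqn{p_i = 2 (1 + F_i)^{-1}
#'   e^{-G_{p,i}/H_i}}, decreasing in \eqn{F_i}. Both are clamped to
#'   \[0, 1\].
#' @return Object of class \code{regulatory_params}.
#' @export
regulatory_params <- function(n, Gp = log(3), H = 1, GA = 0, GR = 0,
                              Phi = 2, hA = 1, hR = 1,
                              exponent_base = n,
                              exponent_mode = c("genes", "regulators"),
                              binding_form = c("occupancy", "literal")) {
  bc <- function(v, what) {
    if (length(v) == 1L) v <- rep(as.numeric(v), n)
    if (length(v) != n || any(!is.finite(v)))
      stop(what, " must be a finite scalar or length-n vector")
    v
  }
  H <- bc(H, "H"); hA <- as.numeric(hA); hR <- as.numeric(hR)
  if (any(H <= 0) || hA <= 0 || hR <= 0)
    stop("H, hA and hR must be strictly positive")
  if (exponent_base < 1) stop("exponent_base must be >= 1")
  structure(
    list(n = as.integer(n), Gp = bc(Gp, "Gp"), H = H, GA = bc(GA, "GA"),
         GR = bc(GR, "GR"), Phi = bc(Phi, "Phi"), hA = hA, hR = hR,
         exponent_base = as.numeric(exponent_base),
         exponent_mode = match.arg(exponent_mode),
         binding_form = match.arg(binding_form)),
    class = "regulatory_params")
}

#' Kinetic parameters
#'
#' Scalar rate arguments are broadcast to length \code{n}. Units: rates per
#' minute, time in minutes, concentrations in molecules. Exactly one of the
#' stochastic (\code{gamma > 0}, which forces \code{tau = 0}) and delay
#' (\code{tau > 0}) mechanisms may be active in a run.
#'
#' @param n Number of genes.
#' @param Kx Transcription rates (molecules/min); per-genotype, normally the
#'   product of the shared expression rates P and a marker-effect row.
#' @param Ks Translation rates (proteins per mRNA per minute).
#' @param Zx,Zs mRNA / protein degradation rates (1/min).
#' @param tau Regulatory/translational time delay (minutes).
#' @param gamma Multiplicative noise amplitude.
#' @param sigma_q Standard deviation of the stochastic diagonal elements.
#' @param Tmax Simulation time span (minutes).
#' @return Object of class \code{kinetic_params}.
#' @export
kinetic_params <- function(n, Kx = 10, Ks = 1, Zx = 0.05, Zs = 0.05,
                           tau = 0, gamma = 0, sigma_q = 0.1, Tmax = 1000) {
  bc <- function(v, what) {
    if (length(v) == 1L) v <- rep(as.numeric(v), n)
    if (length(v) != n || any(!is.finite(v)) || any(v <= 0))
      stop(what, " must be positive, scalar or length n")
    v
  }
  if (tau < 0 || gamma < 0 || sigma_q < 0)
    stop("tau, gamma and sigma_q must be nonnegative")
  if (tau > 0 && gamma > 0)
    stop("stochastic mode forces tau = 0: tau > 0 and gamma > 0 cannot both be set")
  if (Tmax <= 0) stop("Tmax must be positive")
  structure(
    list(n = as.integer(n), Kx = bc(Kx, "Kx"), Ks = bc(Ks, "Ks"),
         Zx = bc(Zx, "Zx"), Zs = bc(Zs, "Zs"), tau = as.numeric(tau),
         gamma = as.numeric(gamma), sigma_q = as.numeric(sigma_q),
         Tmax = as.numeric(Tmax)),
    class = "kinetic_params")
}

#' Regulator-masked concentrations
#'
#' Entrywise product of (delayed) protein concentrations with column i of an
#' adjacency matrix: nonzero only at the regulators of gene i.
#'
#' @param s_delayed Length-n protein concentrations s(t - tau).
#' @param adjacency n x n binary adjacency (entry (j,i) = 1: j regulates i).
#' @param i Target gene index.
#' @return Length-n vector.
#' @export
masked_concentrations <- function(s_delayed, adjacency, i) {
  if (length(s_delayed) != nrow(adjacency) ||
      nrow(adjacency) != ncol(adjacency))
    stop("dimension mismatch between s_delayed and adjacency")
  if (i < 1L || i > ncol(adjacency)) stop("gene index out of range")
  as.numeric(s_delayed * adjacency[, i])
}

exponent_of <- function(reg, n_regulators = NULL) {
  if (reg$exponent_mode == "regulators" && !is.null(n_regulators))
    pmax(1, n_regulators) else reg$exponent_base
}

#' Activator factor
#'
#' Entrywise \eqn{[(h_A + s_j^2 e^{-G_{A,j}} \Phi_j) /
#' (h_A + s_j^2 e^{-G_{A,j}})]^{1/n_b}} on a masked activator-concentration
#' vector. Entries are 1 where the concentration is 0 (non-regulators) and
#' exceed 1 exactly where \eqn{\Phi_j > 1} and \eqn{s_j > 0}.
#'
#' @param sA Masked activator concentrations (length n, nonnegative).
#' @param reg A [regulatory_params()].
#' @param exponent Optional override of the 1/n exponent base.
#' @return Length-n vector of factors.
#' @export
activator_factor <- function(sA, reg, exponent = reg$exponent_base) {
  if (any(sA < 0)) stop("concentrations must be nonnegative")
  b <- sA^2 * exp(-reg$GA)
  ((reg$hA + b * reg$Phi) / (reg$hA + b))^(1 / exponent)
}

#' Repressor factor
#'
#' Entrywise \eqn{[1 + h_R s_j^2 e^{-G_{R,j}}]^{-1/n_b}} on a masked
#' repressor-concentration vector. Entries lie in (0, 1\], equal 1 where the
#' concentration is 0, and decrease strictly in \eqn{s_j}.
#'
#' @inheritParams activator_factor
#' @param sR Masked repressor concentrations (length n, nonnegative).
#' @return Length-n vector of factors.
#' @export
repressor_factor <- function(sR, reg, exponent = reg$exponent_base) {
  if (any(sR < 0)) stop("concentrations must be nonnegative")
  (1 + reg$hR * sR^2 * exp(-reg$GR))^(-1 / exponent)
}

#' Scalar regulatory factor F_ii
#'
#' Determinant of the product of the diagonal activator- and
#' repressor-factor matrices for one gene: the product of all entries of
#' \code{fA * fR}. Equals 1 for an unregulated gene (all factors 1).
#'
#' @param fA,fR Positive factor vectors from [activator_factor()] /
#'   [repressor_factor()].
#' @return Scalar.
#' @export
regulatory_factor <- function(fA, fR) {
  if (any(fA <= 0) || any(fR <= 0)) stop("factors must be positive")
  prod(fA * fR)
}

#' RNAP II binding probability for one gene
#'
#' Occupancy form (default): \eqn{p_i = 2 / (1 + F_i^{-1} e^{G_{p,i}/H_i})};
#' literal form: \eqn{p_i = 2 (1 + F_i)^{-1} e^{-G_{p,i}/H_i}}. Clamped to
#' \[0, 1\].
#'
#' @param F Positive regulatory factor(s), length n or scalar.
#' @param reg A [regulatory_params()].
#' @return Binding probabilities in \[0, 1\].
#' @export
binding_probability <- function(F, reg) {
  if (any(F <= 0)) stop("regulatory factor must be positive")
  raw <- if (reg$binding_form == "occupancy")
    2 / (1 + exp(reg$Gp / reg$H) / F)
  else
    2 / (1 + F) * exp(-reg$Gp / reg$H)
  pmin(pmax(raw, 0), 1)
}

#' Binding probabilities for all genes of a network
#'
#' Vectorized evaluation of the full kernel: for every gene i, masks the
#' delayed protein vector by the columns of A and R, forms the activator and
#' repressor factors, multiplies them into the scalar regulatory factor
#' \eqn{F_i} and maps through [binding_probability()].
#'
#' @param s Length-n (delayed) protein concentrations.
#' @param reg A [regulatory_params()].
#' @param net A [regulatory_network()].
#' @return Length-n vector of binding probabilities.
#' @export
binding_probabilities <- function(s, reg, net) {
  if (length(s) != net$n_genes) stop("dimension mismatch")
  # factor contributed by gene j as a regulator depends only on s_j, so
  # log F_i = (1/nb) * (t(A) %*% log gA + t(R) %*% log gR)[i]
  b <- s^2 * exp(-reg$GA)
  log_gA <- log(reg$hA + b * reg$Phi) - log(reg$hA + b)
  log_gR <- -log1p(reg$hR * s^2 * exp(-reg$GR))
  acc <- crossprod(net$A, log_gA) + crossprod(net$R, log_gR)
  nb <- if (reg$exponent_mode == "regulators")
    pmax(1, colSums(net$A) + colSums(net$R)) else reg$exponent_base
  F <- exp(as.numeric(acc) / nb)
  binding_probability(F, reg)
}

#' Time derivative of the coupled mRNA/protein state
#'
#' Deterministic part of the dynamics:
#' \eqn{\dot x = K_x \, p(s(t-\tau)) - Z_x x}, \eqn{\dot s = K_s \,
#' x(t-\tau) - Z_s s}.
#'
#' @param x,s Current mRNA and protein concentrations (length n).
#' @param x_delayed,s_delayed Delayed concentrations x(t - tau), s(t - tau).
#' @param kin A [kinetic_params()].
#' @param reg A [regulatory_params()].
#' @param net A [regulatory_network()].
#' @return List with elements \code{dx} and \code{ds}.
#' @export
regulatory_rhs <- function(x, s, x_delayed, s_delayed, kin, reg, net) {
  n <- net$n_genes
  if (length(x) != n || length(s) != n || length(x_delayed) != n ||
      length(s_delayed) != n)
    stop("dimension mismatch in state vectors")
  p <- binding_probabilities(s_delayed, reg, net)
  list(dx = kin$Kx * p - kin$Zx * x,
       ds = kin$Ks * x_delayed - kin$Zs * s)
}

# Closure over precomputed constants; f(t, c, c_lag) on the stacked state
# c = (x, s). Used by both integrators.
make_rhs <- function(kin, reg, net) {
  n <- net$n_genes
  tA <- t(net$A); tR <- t(net$R)
  expGA <- exp(-reg$GA); expGR <- exp(-reg$GR)
  PhiA <- reg$Phi; hA <- reg$hA; hR <- reg$hR
  egH <- exp(reg$Gp / reg$H)
  nb <- if (reg$exponent_mode == "regulators")
    pmax(1, colSums(net$A) + colSums(net$R)) else reg$exponent_base
  occupancy <- reg$binding_form == "occupancy"
  Kx <- kin$Kx; Ks <- kin$Ks; Zx <- kin$Zx; Zs <- kin$Zs
  ix <- seq_len(n); is <- n + ix
  function(t, c_now, c_lag) {
    s_lag <- c_lag[is]
    b <- s_lag * s_lag * expGA
    log_gA <- log(hA + b * PhiA) - log(hA + b)
    log_gR <- -log1p(hR * s_lag * s_lag * expGR)
    F <- exp((as.numeric(tA %*% log_gA) + as.numeric(tR %*% log_gR)) / nb)
    p <- if (occupancy) 2 / (1 + egH / F) else 2 / (1 + F) / egH
    p[p > 1] <- 1
    c(Kx * p - Zx * c_now[ix], Ks * c_lag[ix] - Zs * c_now[is])
  }
}

#' Euler-Maruyama integration (stochastic mode)
#'
#' Fixed-step Euler-Maruyama for the stochastic problem (tau = 0). The step
#' is \code{dt = 5e-4 * Tmax}, i.e. exactly 2000 steps regardless of Tmax.
#' Noise is multiplicative: per component,
#' \code{c <- c + f(c) dt + gamma * c * eta} with
#' \code{eta ~ Normal(0, sigma_q^2 * dt)} i.i.d.; states are clamped at 0
#' after each step.
#'
#' @param initial Length-2n stacked initial state (x then s), or length-n
#'   (recycled to both blocks).
#' @param kin A [kinetic_params()] with \code{tau = 0}.
#' @param reg A [regulatory_params()].
#' @param net A [regulatory_network()].
#' @param seed Integer seed; trajectories are reproducible per seed.
#' @return Object of class \code{trajectory}: list with \code{times},
#'   \code{x} (time x n mRNA matrix), \code{s} (protein matrix), \code{mode}.
#' @export
integrate_em <- function(initial, kin, reg, net, seed = 1L) {
  if (kin$tau > 0) stop("stochastic mode requires tau = 0")
  n <- net$n_genes
  c0 <- stack_state(initial, n)
  f <- make_rhs(kin, reg, net)
  dt <- 5e-4 * kin$Tmax
  n_steps <- 2000L
  set.seed(as.integer(seed))
  states <- matrix(0, n_steps + 1L, 2L * n)
  states[1L, ] <- c0
  c_now <- c0
  sdt <- kin$sigma_q * sqrt(dt)
  g <- kin$gamma
  for (k in seq_len(n_steps)) {
    drift <- f((k - 1L) * dt, c_now, c_now)
    c_now <- c_now + drift * dt
    if (g > 0)
      c_now <- c_now + g * c_now * stats::rnorm(2L * n, 0, sdt)
    c_now[c_now < 0] <- 0
    states[k + 1L, ] <- c_now
  }
  trajectory(times = seq(0, kin$Tmax, by = dt), states = states, n = n,
             mode = if (g > 0) "stochastic" else "deterministic")
}

stack_state <- function(initial, n) {
  if (length(initial) == n) initial <- c(initial, initial)
  if (length(initial) != 2L * n)
    stop("initial state must have length n or 2n")
  if (any(initial < 0)) stop("initial state must be nonnegative")
  as.numeric(initial)
}

trajectory <- function(times, states, n, mode) {
  structure(list(times = times,
                 x = states[, seq_len(n), drop = FALSE],
                 s = states[, n + seq_len(n), drop = FALSE],
                 mode = mode),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory (", x$mode, "): ", ncol(x$x), " genes, ",
      length(x$times), " time points on [0, ",
      format(max(x$times)), "]\n", sep = "")
  invisible(x)
}

#' Embedded Runge-Kutta solver with time delay (dde23-style)
#'
#' Integrates \code{y' = f(t, y, y(t - tau))} with the Bogacki-Shampine
#' embedded 3(2) pair, continuous extension by cubic Hermite interpolation of
#' the stored solution (used to evaluate the delayed state), constant
#' pre-history equal to the initial state for t <= 0, initial step size from
#' the slope at the initial time, and adaptive step-size control. For
#' \code{tau > 0} steps are capped at \code{tau} so stage lags always fall in
#' already-accepted history.
#'
#' @param f Function \code{f(t, y, y_lag)} returning dy/dt.
#' @param y0 Initial state vector.
#' @param tau Nonnegative delay; 0 gives a plain adaptive ODE solve.
#' @param tmax End time.
#' @param rel_tol,abs_tol Relative / absolute local error tolerances.
#' @param max_steps Step budget before failure.
#' @return List with \code{times} (row-ordered) and \code{states}
#'   (matrix, one row per accepted time).
#' @export
rk23_solve <- function(f, y0, tau = 0, tmax, rel_tol = 1e-3, abs_tol = 1e-6,
                       max_steps = 1e5) {
  y0 <- as.numeric(y0)
  d <- length(y0)
  cap <- 1024L
  ts <- numeric(cap); ys <- matrix(0, cap, d); fs <- matrix(0, cap, d)
  n_pts <- 1L
  ts[1L] <- 0
  ys[1L, ] <- y0

  # delayed-state lookup: constant history for t <= 0, cubic Hermite inside
  # accepted segments
  lag_state <- function(t_lag) {
    if (t_lag <= 0) return(y0)
    k <- findInterval(t_lag, ts[seq_len(n_pts)])
    if (k >= n_pts) return(ys[n_pts, ])
    h <- ts[k + 1L] - ts[k]
    th <- (t_lag - ts[k]) / h
    h00 <- (1 + 2 * th) * (1 - th)^2
    h10 <- th * (1 - th)^2
    h01 <- th^2 * (3 - 2 * th)
    h11 <- th^2 * (th - 1)
    h00 * ys[k, ] + h * h10 * fs[k, ] + h01 * ys[k + 1L, ] +
      h * h11 * fs[k + 1L, ]
  }

  grow <- function() {
    cap2 <- 2L * cap
    ts2 <- numeric(cap2); ts2[seq_len(n_pts)] <- ts[seq_len(n_pts)]
    ys2 <- matrix(0, cap2, d); ys2[seq_len(n_pts), ] <- ys[seq_len(n_pts), ]
    fs2 <- matrix(0, cap2, d); fs2[seq_len(n_pts), ] <- fs[seq_len(n_pts), ]
    ts <<- ts2; ys <<- ys2; fs <<- fs2; cap <<- cap2
  }

  # with tau = 0 the "delayed" argument is just the current stage state
  fval <- if (tau == 0) function(t, y) f(t, y, y) else
    function(t, y) f(t, y, lag_state(t - tau))

  t <- 0
  y <- y0
  k1 <- fval(t, y)
  fs[1L, ] <- k1
  # initial step from the initial slope
  sc <- abs_tol + rel_tol * abs(y)
  d0 <- sqrt(mean((y / sc)^2)); d1 <- sqrt(mean((k1 / sc)^2))
  h <- if (d1 > 1e-10) 0.01 * d0 / d1 else 1e-6 * tmax
  h <- min(max(h, 1e-10 * tmax), tmax / 10)
  if (tau > 0) h <- min(h, tau)

  steps <- 0L
  while (t < tmax) {
    if (steps >= max_steps)
      stop("rk23_solve: tolerance not achieved within ", max_steps,
           " steps (t = ", format(t), ", h = ", format(h), ")")
    steps <- steps + 1L
    h <- min(h, tmax - t)
    k2 <- fval(t + h / 2, y + h / 2 * k1)
    k3 <- fval(t + 3 * h / 4, y + 3 * h / 4 * k2)
    y_new <- y + h * (2 * k1 + 3 * k2 + 4 * k3) / 9
    k4 <- fval(t + h, y_new)
    err <- h * (-5 * k1 + 6 * k2 + 8 * k3 - 9 * k4) / 72
    sc <- abs_tol + rel_tol * pmax(abs(y), abs(y_new))
    err_norm <- max(abs(err) / sc)
    if (is.na(err_norm) || !is.finite(err_norm)) err_norm <- 2
    if (err_norm <= 1) {
      t <- t + h
      y <- y_new
      k1 <- k4  # FSAL
      if (n_pts + 1L > cap) grow()
      n_pts <- n_pts + 1L
      ts[n_pts] <- t; ys[n_pts, ] <- y; fs[n_pts, ] <- k4
    }
    fac <- if (err_norm > 0) 0.9 * err_norm^(-1 / 3) else 5
    h <- h * min(5, max(0.2, fac))
    if (tau > 0) h <- min(h, tau)
  }
  list(times = ts[seq_len(n_pts)], states = ys[seq_len(n_pts), , drop = FALSE])
}

#' Delay / deterministic integration of the regulatory dynamics
#'
#' Integrates the coupled mRNA/protein system with [rk23_solve()]. With
#' \code{tau > 0} translation uses x(t - tau) and regulation uses s(t - tau)
#' (both with the same delay); with \code{tau = 0} this is the deterministic
#' ODE solve. Requires \code{gamma = 0}.
#'
#' @inheritParams integrate_em
#' @param rel_tol,abs_tol Solver tolerances.
#' @return A \code{trajectory} (see [integrate_em()]).
#' @export
integrate_dde <- function(initial, kin, reg, net, rel_tol = 1e-3,
                          abs_tol = 1e-6) {
  if (kin$gamma > 0) stop("delay/deterministic mode requires gamma = 0")
  n <- net$n_genes
  c0 <- stack_state(initial, n)
  f <- make_rhs(kin, reg, net)
  sol <- rk23_solve(f, c0, tau = kin$tau, tmax = kin$Tmax,
                    rel_tol = rel_tol, abs_tol = abs_tol)
  sol$states[sol$states < 0] <- 0
  trajectory(times = sol$times, states = sol$states, n = n,
             mode = if (kin$tau > 0) "delay" else "deterministic")
}

#' Simulate one genotype
#'
#' Integrates the dynamics for one genotype's transcription rates from the
#' all-ones initial state over \[0, Tmax\] and returns the trajectory
#' together with per-gene time averages of mRNA and protein over the final
#' \code{1 - burn_in} share of the time span (default: the first 20% is
#' discarded to remove initial-condition transients).
#'
#' @param Kx_j Length-n transcription-rate vector for the genotype (see
#'   [genotype_transcription_rates()]).
#' @param kin A [kinetic_params()]; its \code{Kx} slot is replaced by
#'   \code{Kx_j}.
#' @param reg A [regulatory_params()].
#' @param net A [regulatory_network()].
#' @param mode One of \code{"deterministic"}, \code{"stochastic"},
#'   \code{"delay"}.
#' @param seed Integer seed (used in stochastic mode).
#' @param burn_in Leading fraction of the span excluded from averages.
#' @param rel_tol,abs_tol Tolerances for the RK modes.
#' @param genotype_id Label attached to the result and to error messages.
#' @return Object of class \code{gene_products}: list with
#'   \code{genotype_id}, \code{trajectory}, \code{mean_mrna},
#'   \code{mean_protein}.
#' @export
simulate_genotype <- function(Kx_j, kin, reg, net,
                              mode = c("deterministic", "stochastic", "delay"),
                              seed = 1L, burn_in = 0.2,
                              rel_tol = 1e-3, abs_tol = 1e-6,
                              genotype_id = "genotype") {
  mode <- match.arg(mode)
  if (length(Kx_j) != net$n_genes || any(Kx_j <= 0))
    stop("Kx_j must be a positive length-n vector")
  kin$Kx <- as.numeric(Kx_j)
  initial <- rep(1, 2L * net$n_genes)
  traj <- tryCatch(switch(mode,
    stochastic = {
      kin$tau <- 0
      integrate_em(initial, kin, reg, net, seed = seed)
    },
    delay = {
      kin$gamma <- 0
      if (kin$tau <= 0) stop("delay mode requires tau > 0")
      integrate_dde(initial, kin, reg, net, rel_tol, abs_tol)
    },
    deterministic = {
      kin$gamma <- 0; kin$tau <- 0
      integrate_dde(initial, kin, reg, net, rel_tol, abs_tol)
    }), error = function(e)
      stop("simulation failed for ", genotype_id, ": ",
           conditionMessage(e), call. = FALSE))
  avg <- time_average(traj, burn_in)
  structure(list(genotype_id = genotype_id, trajectory = traj,
                 mean_mrna = avg$mean_mrna, mean_protein = avg$mean_protein),
            class = "gene_products")
}
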