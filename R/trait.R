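# Omnigenic trait construction and G-by-G / G-by-E studies.
#
# The trait of individual j is the weighted sum over core genes of its
# time-averaged core-gene protein products normalized by the reference
# genotype's products: y_j = sum_i W_ji * sbar_ji / sbar_ri.

#' Burn-in-corrected time averages of a trajectory
#'
#' Trapezoidal time average per gene over \[burn_in * Tmax, Tmax\]; the value
#' at the window start is obtained by linear interpolation so the average is
#' exact for piecewise-linear trajectories.
#'
#' @param trajectory A \code{trajectory} from [integrate_em()] /
#'   [integrate_dde()].
#' @param burn_in Leading fraction of the time span to discard, in \[0, 1).
#' @return List with \code{mean_mrna} and \code{mean_protein} (length-n).
#' @export
time_average <- function(trajectory, burn_in = 0.2) {
  if (burn_in < 0 || burn_in >= 1) stop("burn_in must be in [0, 1)")
  times <- trajectory$times
  if (length(times) < 2L) stop("empty averaging window: trajectory too short")
  t0 <- times[1L] + burn_in * (times[length(times)] - times[1L])
  list(mean_mrna = trapezoid_means(times, trajectory$x, t0),
       mean_protein = trapezoid_means(times, trajectory$s, t0))
}

trapezoid_means <- function(times, values, t0) {
  keep <- times >= t0
  if (sum(keep) < 1L) stop("empty averaging window")
  t_win <- times[keep]
  v_win <- values[keep, , drop = FALSE]
  if (t_win[1L] > t0) {
    # interpolate the boundary point
    k <- max(which(times < t0))
    w <- (t0 - times[k]) / (times[k + 1L] - times[k])
    v0 <- (1 - w) * values[k, ] + w * values[k + 1L, ]
    t_win <- c(t0, t_win)
    v_win <- rbind(v0, v_win)
  }
  if (length(t_win) < 2L) return(as.numeric(v_win[1L, ]))
  dt <- diff(t_win)
  mid <- (v_win[-1L, , drop = FALSE] + v_win[-nrow(v_win), , drop = FALSE]) / 2
  as.numeric(crossprod(mid, dt)) / sum(dt)
}

#' Normalize core-gene products by the reference genotype
#'
#' Entrywise division of each individual's time-averaged products by the
#' reference genotype's products; the reference's own row maps to all ones.
#'
#' @param pop_products m x nc matrix of time-averaged products.
#' @param ref_products Length-nc strictly positive reference products.
#' @return m x nc matrix S-bar.
#' @export
normalize_products <- function(pop_products, ref_products) {
  pop_products <- as.matrix(pop_products)
  if (ncol(pop_products) != length(ref_products))
    stop("shape mismatch between pop_products and ref_products")
  bad <- which(ref_products <= 0)
  if (length(bad))
    stop("reference product nonpositive for core gene ", bad[1L])
  sweep(pop_products, 2L, ref_products, "/")
}

#' Trait values from normalized core-gene products
#'
#' \code{y_j = sum_i W_ji * Sbar_ji}: the row sums of the Hadamard product
#' of the weight matrix and the normalized products.
#'
#' @param Sbar m x nc matrix of normalized products.
#' @param W Weight matrix (m x nc), or a length-nc vector replicated across
#'   individuals.
#' @return Length-m numeric trait vector.
#' @export
compute_trait <- function(Sbar, W) {
  Sbar <- as.matrix(Sbar)
  if (is.null(dim(W))) {
    if (length(W) != ncol(Sbar)) stop("weight length must equal ncol(Sbar)")
    W <- matrix(W, nrow(Sbar), ncol(Sbar), byrow = TRUE)
  }
  if (!all(dim(W) == dim(Sbar))) stop("shape mismatch between W and Sbar")
  rowSums(W * Sbar)
}

#' Standardized expression level (s.e.l.)
#'
#' Subtracts the mean and divides by the standard deviation of a series.
#'
#' @param series Numeric vector (nonconstant).
#' @return Standardized series with mean 0 and sd 1.
#' @export
standardized_expression <- function(series) {
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant series")
  (series - mean(series)) / s
}

#' Regulator-target correlations of standardized expression
#'
#' Pearson correlation between each regulator's and target's standardized
#' expression series, one row per directed regulatory edge, labelled by edge
#' type. Constant series are excluded with a warning.
#'
#' @param series Matrix, one column per gene (e.g. mRNA over the retained
#'   time window).
#' @param network A [regulatory_network()].
#' @return Data frame with columns \code{regulator}, \code{target},
#'   \code{type}, \code{correlation}.
#' @export
regulatory_correlations <- function(series, network) {
  series <- as.matrix(series)
  if (ncol(series) != network$n_genes)
    stop("series must have one column per gene")
  sds <- apply(series, 2L, stats::sd)
  edges <- rbind(
    cbind(which(network$A == 1, arr.ind = TRUE), type = 1),
    cbind(which(network$R == 1, arr.ind = TRUE), type = 2))
  if (!nrow(edges))
    return(data.frame(regulator = integer(0), target = integer(0),
                      type = character(0), correlation = numeric(0)))
  keep <- sds[edges[, 1]] > 0 & sds[edges[, 2]] > 0
  if (any(!keep))
    warning("excluding ", sum(!keep), " edge(s) with constant series")
  edges <- edges[keep, , drop = FALSE]
  data.frame(
    regulator = as.integer(edges[, 1]),
    target = as.integer(edges[, 2]),
    type = c("activation", "repression")[edges[, 3]],
    correlation = vapply(seq_len(nrow(edges)), function(k)
      stats::cor(series[, edges[k, 1]], series[, edges[k, 2]]), numeric(1)))
}

#' Simulate gene products for every genotype in a population
#'
#' Runs [simulate_genotype()] for each individual with per-genotype seeds
#' derived from the master seed and the genotype index, so results are
#' independent of execution order and worker count.
#'
#' @param pop A [genotype_population()].
#' @param net A [regulatory_network()].
#' @param reg A [regulatory_params()].
#' @param kin A [kinetic_params()].
#' @param P Length-n shared expression rates (see
#'   [sample_expression_rates()]).
#' @param M m x n marker-effect matrix (see [marker_effect_matrix()]).
#' @param mode,burn_in,rel_tol,abs_tol Passed to [simulate_genotype()].
#' @param seed Master seed.
#' @param workers Worker processes for [parallel_map_genotypes()].
#' @return List of \code{gene_products}, one per individual, in population
#'   order.
#' @export
simulate_population <- function(pop, net, reg, kin, P, M,
                                mode = "deterministic", seed = 1L,
                                burn_in = 0.2, rel_tol = 1e-3,
                                abs_tol = 1e-6, workers = 1L) {
  m <- nrow(pop$Mpop)
  parallel_map_genotypes(seq_len(m), function(j) {
    res <- simulate_genotype(
      genotype_transcription_rates(P, M, j), kin, reg, net,
      mode = mode, seed = genotype_seed(seed, j), burn_in = burn_in,
      rel_tol = rel_tol, abs_tol = abs_tol,
      genotype_id = pop$individual_ids[j])
    res$trajectory <- NULL  # keep only the averages at population scale
    res
  }, workers = workers)
}

# per-genotype stream seed; stays below 2^31 - 1
genotype_seed <- function(master, j) {
  as.integer(((as.numeric(master) %% 100000) * 20011 + 7 * as.numeric(j) + 1) %%
               2147483647)
}

#' Genotypic trait values for a population
#'
#' Full trait pipeline for fixed expression rates: simulates every genotype
#' plus the reference genotype, normalizes core-gene protein products by the
#' reference, and applies the core-gene weights.
#'
#' @inheritParams simulate_population
#' @param ref Reference genotype vector; default computed from \code{pop}.
#' @return List with \code{trait} (length-m), \code{Sbar}, \code{products}
#'   (m x nc core protein averages), \code{ref_products}, and
#'   \code{all_products} (the full list from [simulate_population()]).
#' @export
population_trait <- function(pop, net, reg, kin, P, M,
                             ref = reference_genotype(pop),
                             mode = "deterministic", seed = 1L,
                             burn_in = 0.2, rel_tol = 1e-3, abs_tol = 1e-6,
                             workers = 1L) {
  if (!length(net$core_genes))
    stop("network has no core genes; cannot build a trait")
  ref_run <- simulate_genotype(P, kin, reg, net, mode = mode,
                               seed = genotype_seed(seed, 0L),
                               burn_in = burn_in, rel_tol = rel_tol,
                               abs_tol = abs_tol, genotype_id = "reference")
  products <- simulate_population(pop, net, reg, kin, P, M, mode = mode,
                                  seed = seed, burn_in = burn_in,
                                  rel_tol = rel_tol, abs_tol = abs_tol,
                                  workers = workers)
  core <- net$core_genes
  core_prod <- do.call(rbind, lapply(products, function(g)
    g$mean_protein[core]))
  ref_prod <- ref_run$mean_protein[core]
  Sbar <- normalize_products(core_prod, ref_prod)
  list(trait = compute_trait(Sbar, net$core_weights),
       Sbar = Sbar, products = core_prod, ref_products = ref_prod,
       all_products = products)
}

#' Genomic-variance response to the G-by-G parameter kappa
#'
#' Reruns the full genotype-to-trait pipeline for each value of kappa with
#' identical seeds and network, and reports the genomic variance Var(y) and
#' trait mean. Expression rates are resampled per kappa from the same seed
#' (common random numbers), so at kappa = 0 every individual is identical
#' and the variance is exactly zero.
#'
#' @inheritParams population_trait
#' @param kappa_grid Numeric vector of kappa values in \[0, 1\].
#' @param P_mu Mean expression rate.
#' @return Data frame with columns \code{kappa}, \code{variance},
#'   \code{mean}.
#' @export
gxg_variance_curve <- function(pop, net, reg, kin, kappa_grid, P_mu = 10,
                               seed = 1L, mode = "deterministic",
                               burn_in = 0.2, rel_tol = 1e-3,
                               abs_tol = 1e-6, workers = 1L) {
  ref <- reference_genotype(pop)
  n <- ncol(pop$Mpop)
  out <- lapply(kappa_grid, function(kappa) {
    P <- sample_expression_rates(P_mu, kappa, n, seed = seed)
    M <- marker_effect_matrix(pop, ref, kappa)
    tr <- population_trait(pop, net, reg, kin, P, M, ref = ref, mode = mode,
                           seed = seed, burn_in = burn_in, rel_tol = rel_tol,
                           abs_tol = abs_tol, workers = workers)$trait
    data.frame(kappa = kappa, variance = stats::var(tr), mean = mean(tr))
  })
  do.call(rbind, out)
}

#' Environment model for G-by-E studies
#'
#' A virtual environment perturbs the expectation of the transcription rates:
#' per replicate, each gene's rate expectation is resampled from
#' Normal(mu_x, phi * mu_x^2), so sqrt(phi) is the coefficient of variation
#' induced by the environment. phi is related to the environmental variance
#' by phi = omega * sigma_env2; only phi enters the computation.
#'
#' @param phi Nonnegative G-by-E response parameter.
#' @param n_replicates Phenotype replicates per environment (>= 1).
#' @param sigma_env2 Environmental variance (bookkeeping only).
#' @param omega Proportionality between phi and sigma_env2 (bookkeeping
#'   only).
#' @return Object of class \code{environment_model}.
#' @export
environment_model <- function(phi, n_replicates = 10L, sigma_env2 = NULL,
                              omega = 1) {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi < 0)
    stop("phi must be a nonnegative real")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (omega <= 0) stop("omega must be positive")
  structure(list(phi = phi, n_replicates = as.integer(n_replicates),
                 sigma_env2 = sigma_env2 %||% phi / omega, omega = omega),
            class = "environment_model")
}

#' Sample environment-perturbed expression rates
#'
#' Elementwise draw from Normal(mu_x, phi * mu_x^2), truncated below at
#' 1e-6 * mu_x by resampling. With phi = 0 the expectation is returned
#' exactly.
#'
#' @param mu_x Positive length-n vector of rate expectations.
#' @param phi Nonnegative G-by-E response parameter.
#' @param seed Integer seed.
#' @return Positive length-n vector.
#' @export
sample_environment_rates <- function(mu_x, phi, seed = 1L) {
  if (any(mu_x <= 0)) stop("mu_x must be positive")
  if (phi < 0) stop("phi must be nonnegative")
  set.seed(as.integer(seed))
  sdv <- sqrt(phi) * mu_x
  p <- stats::rnorm(length(mu_x), mean = mu_x, sd = sdv)
  eps <- 1e-6 * mu_x
  bad <- which(p < eps)
  while (length(bad)) {
    p[bad] <- stats::rnorm(length(bad), mean = mu_x[bad], sd = sdv[bad])
    bad <- bad[p[bad] < eps[bad]]
  }
  p
}

#' G-by-E study for one environment
#'
#' Runs \code{n_replicates} phenotype simulations for a fixed environment:
#' per replicate the transcription-rate expectations are resampled from
#' Normal(mu_x, phi * mu_x^2) (truncated positive), genotype modulation by
#' the marker-effect matrix applies multiplicatively, and the full
#' population is simulated. With phi = 0 every replicate reproduces the
#' genotypic values exactly.
#'
#' @inheritParams population_trait
#' @param env An [environment_model()].
#' @param mu_x Length-n rate expectations (the once-sampled expression rates
#'   of the G-by-G stage).
#' @return List with \code{genotypic} (length-m genotypic values) and
#'   \code{phenotypes} (m x n_replicates matrix).
#' @export
gxe_simulate <- function(pop, net, reg, kin, mu_x, M, env,
                         ref = reference_genotype(pop), seed = 1L,
                         mode = "deterministic", burn_in = 0.2,
                         rel_tol = 1e-3, abs_tol = 1e-6, workers = 1L) {
  stopifnot(inherits(env, "environment_model"))
  genotypic <- population_trait(pop, net, reg, kin, mu_x, M, ref = ref,
                                mode = mode, seed = seed, burn_in = burn_in,
                                rel_tol = rel_tol, abs_tol = abs_tol,
                                workers = workers)$trait
  phenotypes <- vapply(seq_len(env$n_replicates), function(r) {
    P_r <- sample_environment_rates(mu_x, env$phi,
                                    seed = genotype_seed(seed + 499L, r))
    population_trait(pop, net, reg, kin, P_r, M, ref = ref, mode = mode,
                     seed = seed, burn_in = burn_in, rel_tol = rel_tol,
                     abs_tol = abs_tol, workers = workers)$trait
  }, numeric(nrow(pop$Mpop)))
  list(genotypic = genotypic, phenotypes = phenotypes)
}

#' Genomic and environmental variance components
#'
#' \code{sigma_g2} is the variance of the genotypic values across
#' individuals; \code{sigma_e2} is the mean over replicates of the variance
#' (across individuals) of the deviation of each phenotype replicate from
#' the genotypic value.
#'
#' @param phenotypes m x r matrix of phenotype replicates.
#' @param genotypic Length-m genotypic values.
#' @return List with \code{sigma_g2} and \code{sigma_e2}.
#' @export
variance_components <- function(phenotypes, genotypic) {
  phenotypes <- as.matrix(phenotypes)
  if (nrow(phenotypes) != length(genotypic))
    stop("phenotypes and genotypic values differ in length")
  dev_var <- apply(phenotypes - genotypic, 2L, stats::var)
  list(sigma_g2 = stats::var(genotypic), sigma_e2 = mean(dev_var))
}
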