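# End-to-end orchestration: network -> genotypes -> dynamics -> trait,
# deterministic parallel execution, output files and run manifest.

#' Deterministic parallel map over genotypes
#'
#' Applies \code{fun} to each element of \code{indices} using up to
#' \code{workers} forked processes (on Unix; sequential elsewhere). Because
#' every per-genotype random stream is seeded from the master seed and the
#' genotype index, results are identical to sequential execution for any
#' worker count.
#'
#' @param indices Vector of genotype indices (may be empty).
#' @param fun Function of one index.
#' @param workers Number of worker processes.
#' @return List of results in input order.
#' @export
parallel_map_genotypes <- function(indices, fun, workers = 1L) {
  if (!length(indices)) return(list())
  if (workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(indices, fun, mc.cores = workers,
                              mc.preschedule = TRUE)
    errs <- vapply(res, inherits, logical(1), what = "try-error")
    if (any(errs))
      stop("worker failure for genotype index ", indices[which(errs)[1L]],
           ": ", attr(res[[which(errs)[1L]]], "condition")$message)
    res
  } else {
    lapply(indices, fun)
  }
}

config_network <- function(cfg) {
  if (nzchar(cfg$network_prefix)) {
    core <- config_core(cfg)
    read_network(cfg$network_prefix, core_genes = core$locus,
                 core_weights = core$weight)
  } else {
    core <- config_core(cfg)
    specs <- lapply(1:3, function(d)
      basal_geometry_spec(d, gene_fraction = cfg$basal_fractions[d],
                          shape_params = cfg[[paste0("basal", d, "_shape")]]))
    generate_network(cfg$n_genes, specs, edge_rate = cfg$edge_rate,
                     merge_iterations = cfg$merge_iterations,
                     activation_fraction = cfg$activation_fraction,
                     core_genes = core$locus, core_weights = core$weight,
                     n_core = cfg$n_core, seed = cfg$seed)
  }
}

config_core <- function(cfg) {
  if (nzchar(cfg$core_file))
    read_core_genes(cfg$core_file, n_loci = cfg$n_genes)
  else
    list(locus = NULL, weight = NULL)
}

config_population <- function(cfg) {
  if (nzchar(cfg$genotype_file)) read_genotypes(cfg$genotype_file)
  else simulate_genotypes(cfg$m_individuals, cfg$n_genes,
                          seed = cfg$seed + 11L,
                          allele_probs = cfg$allele_probs)
}

config_params <- function(cfg, n) {
  list(
    reg = regulatory_params(n, Gp = cfg$gp, H = cfg$h, GA = cfg$ga,
                            GR = cfg$gr, Phi = cfg$phi_a, hA = cfg$h_a,
                            hR = cfg$h_r, exponent_mode = cfg$exponent_mode,
                            binding_form = cfg$binding_form),
    kin = kinetic_params(n, Kx = cfg$p_mu, Ks = cfg$ks, Zx = cfg$zx,
                         Zs = cfg$zs, tau = cfg$tau, gamma = cfg$gamma,
                         sigma_q = cfg$sigma_q, Tmax = cfg$tmax))
}

#' Run the full simulation pipeline
#'
#' Executes network generation (or adjacency load), genotype simulation (or
#' file load), per-genotype dynamics, and trait assembly; writes the N/A/R
#' adjacency files, the genotype file, \code{products.txt},
#' \code{traits.txt} and a run manifest to the output directory. Outputs are
#' byte-identical for identical config and seed, for any worker count.
#'
#' @param cfg A \code{simulation_config} from [parse_config()] /
#'   [default_config()].
#' @return Invisibly, the manifest as a named list (config echo, package
#'   version, master seed, per-stage wall times, output files with MD5
#'   checksums) plus the in-memory \code{trait} result.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage_time <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()

  net <- config_network(cfg)
  if (!length(net$core_genes)) {
    # fall back to random core genes so a trait is always defined
    set.seed(cfg$seed + 202L)
    net$core_genes <- sort(sample.int(net$n_genes,
                                      max(1L, min(cfg$n_core, net$n_genes))))
    net$core_weights <- rep(1 / length(net$core_genes),
                            length(net$core_genes))
  }
  stage_time["network"] <- tic() - t0; t0 <- tic()

  pop <- config_population(cfg)
  if (ncol(pop$Mpop) != net$n_genes)
    stop("pipeline stage 'genotypes': locus count ", ncol(pop$Mpop),
         " does not match network gene count ", net$n_genes)
  stage_time["genotypes"] <- tic() - t0; t0 <- tic()

  prm <- config_params(cfg, net$n_genes)
  P <- sample_expression_rates(cfg$p_mu, cfg$kappa, net$n_genes,
                               seed = cfg$seed + 23L)
  ref <- reference_genotype(pop)
  M <- marker_effect_matrix(pop, ref, cfg$kappa)
  res <- population_trait(pop, net, prm$reg, prm$kin, P, M, ref = ref,
                          mode = cfg$mode, seed = cfg$seed,
                          burn_in = cfg$burn_in, rel_tol = cfg$rel_tol,
                          abs_tol = cfg$abs_tol, workers = cfg$workers)
  stage_time["dynamics"] <- tic() - t0; t0 <- tic()

  out <- function(f) file.path(cfg$outdir, f)
  write_network(net, out("network"))
  write_genotypes(pop, out("genotypes.dat"))
  write_products(res$all_products, out("products.txt"))
  write_traits(pop$individual_ids, res$trait, path = out("traits.txt"))
  files <- c("network.N.grm", "network.A.grm", "network.R.grm",
             "genotypes.dat", "products.txt", "traits.txt")
  stage_time["output"] <- tic() - t0

  manifest <- list(
    package_version = as.character(utils::packageVersion("omnisim")),
    master_seed = cfg$seed,
    config = unclass(cfg),
    stage_seconds = as.list(round(stage_time, 3)),
    files = stats::setNames(
      as.list(unname(tools::md5sum(file.path(cfg$outdir, files)))), files))
  write_manifest(manifest, out("manifest.txt"))
  invisible(c(manifest, list(trait = res$trait, network = net)))
}

#' Write a products table
#'
#' One row per genotype: id, then the n time-averaged mRNA values, then the
#' n time-averaged protein values, whitespace-separated under a header line.
#'
#' @param products List of \code{gene_products} (see
#'   [simulate_population()]).
#' @param path Output path.
#' @export
write_products <- function(products, path) {
  if (!length(products)) {
    writeLines("id", path)
    return(invisible(path))
  }
  n <- length(products[[1L]]$mean_mrna)
  header <- paste(c("id", paste0("x_", seq_len(n)), paste0("s_", seq_len(n))),
                  collapse = " ")
  rows <- vapply(products, function(g)
    paste(c(g$genotype_id,
            format(c(g$mean_mrna, g$mean_protein), digits = 10,
                   trim = TRUE, scientific = FALSE)), collapse = " "),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a traits table
#'
#' One row per genotype: id and genotypic value; in G-by-E mode additional
#' columns hold the phenotype replicates.
#'
#' @param ids Individual ids.
#' @param trait Genotypic values.
#' @param phenotypes Optional m x r replicate matrix.
#' @param path Output path.
#' @export
write_traits <- function(ids, trait, phenotypes = NULL, path) {
  header <- c("id", "trait")
  cols <- list(ids, format(trait, digits = 10, trim = TRUE,
                           scientific = FALSE))
  if (!is.null(phenotypes)) {
    phenotypes <- as.matrix(phenotypes)
    header <- c(header, paste0("pheno_", seq_len(ncol(phenotypes))))
    for (r in seq_len(ncol(phenotypes)))
      cols[[length(cols) + 1L]] <- format(phenotypes[, r], digits = 10,
                                          trim = TRUE, scientific = FALSE)
  }
  writeLines(c(paste(header, collapse = " "),
               do.call(paste, cols)), path)
  invisible(path)
}

write_manifest <- function(manifest, path) {
  lines <- c(
    paste("package_version:", manifest$package_version),
    paste("master_seed:", manifest$master_seed),
    "config:",
    paste0("  ", names(manifest$config), " = ",
           vapply(manifest$config, function(v)
             paste(format(v, digits = 17, trim = TRUE), collapse = ", "),
             character(1))),
    "stage_seconds:",
    paste0("  ", names(manifest$stage_seconds), " = ",
           unlist(manifest$stage_seconds)),
    "files:",
    paste0("  ", names(manifest$files), " md5 ", unlist(manifest$files)))
  writeLines(lines, path)
  invisible(path)
}
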