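# Plain-text configuration files: `key = value` lines, `#` comments,
# case-insensitive keys, exhaustively validated against module preconditions.

config_registry <- function() {
  num_in <- function(lo, hi, what)
    function(v) if (is.na(v) || v < lo || v > hi)
      paste0(what, " must be in [", lo, ", ", hi, "]") else NULL
  pos <- function(what)
    function(v) if (is.na(v) || v <= 0) paste0(what, " must be > 0") else NULL
  nonneg <- function(what)
    function(v) if (is.na(v) || v < 0) paste0(what, " must be >= 0") else NULL
  int_ge <- function(lo, what)
    function(v) if (is.na(v) || v < lo || v != round(v))
      paste0(what, " must be an integer >= ", lo) else NULL

  list(
    seed = list(type = "integer", default = 1L, check = int_ge(0, "seed")),
    m_individuals = list(type = "integer", default = 100L,
                         check = int_ge(1, "m_individuals")),
    n_genes = list(type = "integer", default = 50L,
                   check = int_ge(2, "n_genes")),
    n_core = list(type = "integer", default = 12L,
                  check = int_ge(0, "n_core")),
    mode = list(type = "character", default = "deterministic",
                check = function(v) if (!v %in% c("deterministic",
                                                  "stochastic", "delay"))
                  "mode must be deterministic, stochastic or delay" else NULL),
    tmax = list(type = "numeric", default = 1000, check = pos("Tmax")),
    tau = list(type = "numeric", default = 0, check = nonneg("tau")),
    gamma = list(type = "numeric", default = 0, check = nonneg("gamma")),
    sigma_q = list(type = "numeric", default = 0.1,
                   check = nonneg("sigma_q")),
    rel_tol = list(type = "numeric", default = 1e-3, check = pos("rel_tol")),
    abs_tol = list(type = "numeric", default = 1e-6, check = pos("abs_tol")),
    kappa = list(type = "numeric", default = 0.5,
                 check = num_in(0, 1, "kappa")),
    kappa_grid = list(type = "numeric_vector",
                      default = c(0, 0.25, 0.5, 0.75, 1),
                      check = function(v) if (any(is.na(v) | v < 0 | v > 1))
                        "kappa_grid entries must be in [0, 1]" else NULL),
    phi = list(type = "numeric", default = 0, check = nonneg("phi")),
    phi_grid = list(type = "numeric_vector",
                    default = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
                    check = function(v) if (any(is.na(v) | v < 0))
                      "phi_grid entries must be >= 0" else NULL),
    n_replicates = list(type = "integer", default = 10L,
                        check = int_ge(1, "n_replicates")),
    burn_in = list(type = "numeric", default = 0.2,
                   check = function(v) if (is.na(v) || v < 0 || v >= 1)
                     "burn_in must be in [0, 1)" else NULL),
    p_mu = list(type = "numeric", default = 10, check = pos("P_mu")),
    allele_probs = list(type = "numeric_vector", default = rep(1 / 3, 3),
                        check = function(v)
                          if (length(v) != 3L || any(is.na(v) | v < 0) ||
                              abs(sum(v) - 1) > 1e-9)
                            "allele_probs must be 3 nonnegative reals summing to 1"
                          else NULL),
    basal_fractions = list(type = "numeric_vector", default = c(1, 0, 0),
                           check = function(v)
                             if (length(v) != 3L || any(is.na(v) | v < 0) ||
                                 abs(sum(v) - 1) > 1e-9)
                               "basal_fractions must be 3 fractions summing to 1"
                             else NULL),
    basal1_shape = list(type = "numeric_vector", default = c(1, 0),
                        check = shape_check),
    basal2_shape = list(type = "numeric_vector", default = c(1, 0),
                        check = shape_check),
    basal3_shape = list(type = "numeric_vector", default = c(1, 0),
                        check = shape_check),
    edge_rate = list(type = "numeric", default = 0.02,
                     check = pos("edge_rate")),
    merge_iterations = list(type = "integer", default = 1L,
                            check = int_ge(0, "merge_iterations")),
    activation_fraction = list(type = "numeric", default = 0.5,
                               check = num_in(0, 1, "activation_fraction")),
    gp = list(type = "numeric", default = log(3),
              check = function(v) if (is.na(v)) "Gp must be finite" else NULL),
    h = list(type = "numeric", default = 1, check = pos("H")),
    ga = list(type = "numeric", default = 0,
              check = function(v) if (is.na(v)) "GA must be finite" else NULL),
    gr = list(type = "numeric", default = 0,
              check = function(v) if (is.na(v)) "GR must be finite" else NULL),
    phi_a = list(type = "numeric", default = 2, check = pos("Phi")),
    h_a = list(type = "numeric", default = 1, check = pos("hA")),
    h_r = list(type = "numeric", default = 1, check = pos("hR")),
    exponent_mode = list(type = "character", default = "genes",
                         check = function(v)
                           if (!v %in% c("genes", "regulators"))
                             "exponent_mode must be genes or regulators"
                           else NULL),
    binding_form = list(type = "character", default = "occupancy",
                        check = function(v)
                          if (!v %in% c("occupancy", "literal"))
                            "binding_form must be occupancy or literal"
                          else NULL),
    ks = list(type = "numeric", default = 1, check = pos("Ks")),
    zx = list(type = "numeric", default = 0.05, check = pos("Zx")),
    zs = list(type = "numeric", default = 0.05, check = pos("Zs")),
    workers = list(type = "integer", default = 1L,
                   check = int_ge(1, "workers")),
    outdir = list(type = "character", default = "omnisim-output",
                  check = function(v) NULL),
    genotype_file = list(type = "character", default = "",
                         check = function(v) NULL),
    core_file = list(type = "character", default = "",
                     check = function(v) NULL),
    network_prefix = list(type = "character", default = "",
                          check = function(v) NULL)
  )
}

shape_check <- function(v) {
  if (length(v) != 2L || any(is.na(v)))
    return("shape params must be two reals: flavor, beta")
  if (!v[1] %in% c(-1, 0, 1)) return("shape flavor must be -1, 0 or 1")
  if (v[2] < 0) return("shape beta must be >= 0")
  NULL
}

#' Parse a simulation configuration file
#'
#' Plain-text `key = value` format: one pair per line, `#` starts a comment,
#' keys are case-insensitive, vector values are comma-separated. Unknown
#' keys, type mismatches and constraint violations are errors naming the key
#' and line. Omitted keys take documented defaults.
#'
#' @param path Path to the configuration file.
#' @return A validated named list of class \code{simulation_config}.
#' @export
parse_config <- function(path) {
  registry <- config_registry()
  cfg <- lapply(registry, function(e) e$default)
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(line))) next
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0)
      stop("config parse error at line ", i, ": expected key = value")
    key <- tolower(trimws(substr(line, 1L, eq - 1L)))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    if (!key %in% names(registry))
      stop("unknown config key '", key, "' at line ", i)
    entry <- registry[[key]]
    parsed <- switch(entry$type,
      integer = suppressWarnings(as.integer(val)),
      numeric = suppressWarnings(as.numeric(val)),
      numeric_vector = suppressWarnings(
        as.numeric(trimws(strsplit(val, ",")[[1L]]))),
      character = val)
    if (entry$type != "character" && anyNA(parsed))
      stop("config type error for key '", key, "' at line ", i,
           ": cannot parse '", val, "'")
    msg <- entry$check(parsed)
    if (!is.null(msg))
      stop("config constraint violation for key '", key, "' at line ", i,
           ": ", msg)
    cfg[[key]] <- parsed
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  registry <- config_registry()
  for (key in names(registry)) {
    msg <- registry[[key]]$check(cfg[[key]])
    if (!is.null(msg)) stop("invalid config value for '", key, "': ", msg)
  }
  if (cfg$tau > 0 && cfg$gamma > 0)
    stop("invalid config: tau > 0 and gamma > 0 cannot both be set")
  if (cfg$mode == "delay" && cfg$tau <= 0)
    stop("invalid config: delay mode requires tau > 0")
  if (cfg$mode == "stochastic" && cfg$tau > 0)
    stop("invalid config: stochastic mode forces tau = 0")
  if (cfg$n_core > cfg$n_genes)
    stop("invalid config: n_core exceeds n_genes")
  structure(cfg, class = "simulation_config")
}

#' Default configuration
#'
#' @return The fully defaulted \code{simulation_config}.
#' @export
default_config <- function() {
  validate_config(lapply(config_registry(), function(e) e$default))
}

#' Write a configuration file
#'
#' Inverse of [parse_config()]: \code{parse_config(write_config(cfg))}
#' reproduces \code{cfg}.
#'
#' @param cfg A \code{simulation_config}.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.character(v)) v else
      paste(vapply(v, function(x) format(x, digits = 17), character(1)),
            collapse = ", ")
  }
  writeLines(paste(names(cfg), "=", vapply(cfg, fmt, character(1))), path)
  invisible(path)
}
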