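# Genotype populations and the mapping of SNP polymorphism into per-genotype
# transcription rates via the relative marker-effect matrix.

#' Simulate a genotype population
#'
#' Draws an m x n allele-count matrix with i.i.d. entries from \{0, 1, 2\}.
#'
#' @param m Number of individuals.
#' @param n Number of SNP loci (= genes in the regulatory network).
#' @param seed Integer seed.
#' @param allele_probs Probabilities of counts 0, 1, 2; nonnegative, sum 1.
#' @return Object of class \code{genotype_population}: list with integer
#'   matrix \code{Mpop}, \code{individual_ids}, \code{locus_ids}.
#' @export
simulate_genotypes <- function(m, n, seed = 1L,
                               allele_probs = rep(1 / 3, 3)) {
  if (m < 1L || n < 1L) stop("m and n must be >= 1")
  if (length(allele_probs) != 3L || any(!is.finite(allele_probs)) ||
      any(allele_probs < 0) || abs(sum(allele_probs) - 1) > 1e-9)
    stop("allele_probs must be 3 nonnegative reals summing to 1")
  set.seed(as.integer(seed))
  Mpop <- matrix(sample.int(3L, m * n, replace = TRUE, prob = allele_probs) - 1L,
                 nrow = m, ncol = n)
  genotype_population(Mpop,
                      individual_ids = paste0("ind", seq_len(m)),
                      locus_ids = paste0("loc", seq_len(n)))
}

#' Construct a genotype population from an allele-count matrix
#'
#' @param Mpop m x n matrix with entries in \{0, 1, 2\}.
#' @param individual_ids,locus_ids Unique row / column labels.
#' @return Object of class \code{genotype_population}.
#' @export
genotype_population <- function(Mpop,
                                individual_ids = paste0("ind", seq_len(nrow(Mpop))),
                                locus_ids = paste0("loc", seq_len(ncol(Mpop)))) {
  Mpop <- as.matrix(Mpop)
  if (!all(Mpop %in% c(0L, 1L, 2L)))
    stop("allele counts must be 0, 1 or 2")
  storage.mode(Mpop) <- "integer"
  if (length(individual_ids) != nrow(Mpop) || anyDuplicated(individual_ids))
    stop("individual_ids must be unique, one per row")
  if (length(locus_ids) != ncol(Mpop) || anyDuplicated(locus_ids))
    stop("locus_ids must be unique, one per column")
  structure(list(Mpop = unname(Mpop),
                 individual_ids = as.character(individual_ids),
                 locus_ids = as.character(locus_ids)),
            class = "genotype_population")
}

#' @export
print.genotype_population <- function(x, ...) {
  cat("Genotype population:", nrow(x$Mpop), "individuals x",
      ncol(x$Mpop), "loci\n")
  invisible(x)
}

#' Reference genotype of a population
#'
#' Per locus, the allele count with the highest frequency in the population;
#' ties are broken toward the smallest count so the result is deterministic.
#'
#' @param pop A [genotype_population()].
#' @return Integer vector of length n with entries in \{0, 1, 2\}.
#' @export
reference_genotype <- function(pop) {
  stopifnot(inherits(pop, "genotype_population"))
  apply(pop$Mpop, 2L, function(col) {
    counts <- tabulate(col + 1L, nbins = 3L)
    which.max(counts) - 1L  # which.max returns the first (smallest) maximum
  })
}

#' Relative marker-effect matrix
#'
#' Maps genotype differences from the reference into multiplicative effects
#' on transcription rates: \code{M = 1 + (kappa/3) * (Mpop - Mref)} entrywise,
#' with the G-by-G response parameter \code{kappa} in \[0, 1\]. Since allele
#' differences lie in \[-2, 2\], all entries lie in \[1/3, 5/3\]; the
#' reference genotype's row is all ones.
#'
#' @param pop A [genotype_population()].
#' @param ref Reference genotype (length-n vector of \{0,1,2\}); default
#'   [reference_genotype()] of \code{pop}.
#' @param kappa G-by-G response parameter in \[0, 1\].
#' @return m x n numeric matrix.
#' @export
marker_effect_matrix <- function(pop, ref = reference_genotype(pop), kappa) {
  stopifnot(inherits(pop, "genotype_population"))
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) ||
      kappa < 0 || kappa > 1)
    stop("kappa must be in [0, 1]")
  if (length(ref) != ncol(pop$Mpop) || !all(ref %in% c(0L, 1L, 2L)))
    stop("ref must be a length-n vector with entries in {0, 1, 2}")
  1 + (kappa / 3) * sweep(pop$Mpop, 2L, as.numeric(ref))
}

#' Sample per-gene expression rates
#'
#' Draws the diagonal of the expression-rate matrix P once per simulation
#' from Normal(\code{P_mu}, variance \code{kappa * P_mu}), truncated below at
#' \code{1e-6 * P_mu} by resampling so every rate is strictly positive. The
#' same vector is shared by all genotypes; per-genotype rates are obtained by
#' multiplying with the marker-effect row.
#'
#' @param P_mu Mean expression rate (> 0), molecules per minute.
#' @param kappa Response parameter in \[0, 1\]; the rate variance is
#'   \code{kappa * P_mu}.
#' @param n Number of genes.
#' @param seed Integer seed.
#' @return Length-n positive numeric vector.
#' @export
sample_expression_rates <- function(P_mu, kappa, n, seed = 1L) {
  if (!is.numeric(P_mu) || P_mu <= 0) stop("P_mu must be > 0")
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  set.seed(as.integer(seed))
  eps <- 1e-6 * P_mu
  p <- stats::rnorm(n, mean = P_mu, sd = sqrt(kappa * P_mu))
  bad <- which(p < eps)
  while (length(bad)) {
    p[bad] <- stats::rnorm(length(bad), mean = P_mu, sd = sqrt(kappa * P_mu))
    bad <- bad[p[bad] < eps]
  }
  p
}

#' Genotype-specific transcription rates
#'
#' The diagonal of the per-genotype transcription-rate matrix: the entrywise
#' product of the shared expression rates P with row j of the marker-effect
#' matrix M.
#'
#' @param P Length-n positive vector of expression rates.
#' @param M m x n marker-effect matrix.
#' @param j Individual (row) index.
#' @return Length-n numeric vector.
#' @export
genotype_transcription_rates <- function(P, M, j) {
  if (length(P) != ncol(M)) stop("length(P) must equal ncol(M)")
  if (j < 1L || j > nrow(M)) stop("individual index j out of range")
  as.numeric(P * M[j, ])
}

#' Write / read a genotype file
#'
#' Plain text, one individual per line: an id token followed by n
#' whitespace-separated allele counts in \{0, 1, 2\}. Roundtrip is exact.
#'
#' @param pop A [genotype_population()].
#' @param path File path.
#' @export
write_genotypes <- function(pop, path) {
  stopifnot(inherits(pop, "genotype_population"))
  writeLines(paste(pop$individual_ids,
                   apply(pop$Mpop, 1L, paste, collapse = " ")), path)
  invisible(path)
}

#' @rdname write_genotypes
#' @return \code{read_genotypes}: a [genotype_population()].
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty genotype file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  n <- length(toks[[1L]]) - 1L
  if (n < 1L) stop("genotype parse error at line 1: no allele codes")
  ids <- character(length(lines))
  Mpop <- matrix(0L, length(lines), n)
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) != n + 1L)
      stop("genotype parse error at line ", i, ": expected ", n,
           " codes, found ", length(tk) - 1L)
    codes <- tk[-1L]
    bad <- which(!codes %in% c("0", "1", "2"))
    if (length(bad))
      stop("genotype parse error at line ", i, ": invalid allele code '",
           codes[bad[1L]], "'")
    ids[i] <- tk[1L]
    Mpop[i, ] <- as.integer(codes)
  }
  genotype_population(Mpop, individual_ids = ids,
                      locus_ids = paste0("loc", seq_len(n)))
}

#' Read a core-gene file
#'
#' Plain text, one core gene per line: a locus index (1-based) optionally
#' followed by a weight. When no weights are given, equal weights
#' \code{1/n_core} are assigned.
#'
#' @param path File path.
#' @param n_loci Total locus count, for range validation (optional).
#' @return Data frame with columns \code{locus} and \code{weight}, in file
#'   order.
#' @export
read_core_genes <- function(path, n_loci = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) stop("empty core-gene file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  idx <- integer(length(toks))
  w <- rep(NA_real_, length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (!length(tk) %in% c(1L, 2L))
      stop("core-gene parse error at line ", i, ": expected 1 or 2 tokens")
    v <- suppressWarnings(as.integer(tk[1L]))
    if (is.na(v) || v < 1L)
      stop("core-gene parse error at line ", i, ": invalid index '",
           tk[1L], "'")
    idx[i] <- v
    if (length(tk) == 2L) {
      w[i] <- suppressWarnings(as.numeric(tk[2L]))
      if (is.na(w[i]) || w[i] < 0)
        stop("core-gene parse error at line ", i, ": invalid weight '",
             tk[2L], "'")
    }
  }
  if (anyDuplicated(idx))
    stop("duplicate core-gene index: ", idx[anyDuplicated(idx)])
  if (!is.null(n_loci) && any(idx > n_loci))
    stop("core-gene index out of range: ", max(idx), " > ", n_loci)
  if (all(is.na(w))) {
    w <- rep(1 / length(idx), length(idx))
  } else if (anyNA(w)) {
    stop("core-gene file mixes weighted and unweighted entries")
  }
  data.frame(locus = idx, weight = w)
}
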