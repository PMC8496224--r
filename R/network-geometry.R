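# Synthetic regulatory-network geometry: growth of d-dimensional simplicial
# complexes, merging of basal geometries, and partition into activator /
# repressor subnetworks.

#' Basal geometry specification
#'
#' Describes one basal network geometry grown as a simplicial complex of
#' \code{dimension}-dimensional simplexes (edges, triangles, tetrahedra for
#' d = 1, 2, 3). A full genomic network is assembled from up to three basal
#' geometries, one per dimension, whose \code{gene_fraction}s sum to one.
#'
#' @param dimension Simplex dimension, one of 1, 2 or 3.
#' @param gene_fraction Share of the total gene count allotted to this basal
#'   network, in \[0, 1\].
#' @param shape_params Numeric pair \code{c(flavor, beta)} configuring the
#'   growth process: \code{flavor} in \{-1, 0, 1\} controls how attachment
#'   probability depends on how often a face has already been glued
#'   (\code{1} gives preferential attachment and scale-free geometry,
#'   \code{0} uniform attachment, \code{-1} saturating faces), and
#'   \code{beta >= 0} is an inverse-temperature weighting of random integer
#'   face energies.
#'
#' @return An object of class \code{basal_geometry_spec}.
#' @export
basal_geometry_spec <- function(dimension, gene_fraction = 1,
                                shape_params = c(1, 0)) {
  if (!dimension %in% c(1L, 2L, 3L))
    stop("dimension must be 1, 2 or 3")
  if (!is.numeric(gene_fraction) || length(gene_fraction) != 1L ||
      is.na(gene_fraction) || gene_fraction < 0 || gene_fraction > 1)
    stop("gene_fraction must be a real number in [0, 1]")
  shape_params <- as.numeric(shape_params)
  if (length(shape_params) != 2L || any(!is.finite(shape_params)))
    stop("shape_params must be two finite reals c(flavor, beta)")
  if (!shape_params[1] %in% c(-1, 0, 1))
    stop("shape flavor must be -1, 0 or 1")
  if (shape_params[2] < 0)
    stop("shape beta must be nonnegative")
  structure(
    list(dimension = as.integer(dimension),
         gene_fraction = gene_fraction,
         shape_params = shape_params),
    class = "basal_geometry_spec")
}

#' Grow a d-dimensional simplicial complex
#'
#' Grows a connected network by nonequilibrium simplicial evolution: starting
#' from a single d-simplex, each step attaches one new node by gluing a new
#' d-simplex onto an existing (d-1)-face. The face is selected with
#' probability proportional to \code{exp(-beta * energy) * (1 + flavor * n)},
#' where \code{n} counts how many times the face has already been glued
#' beyond its first incidence; with \code{flavor = -1} a face saturates after
#' one gluing. Face energies are sums of integer node energies drawn
#' uniformly from 0..10 (irrelevant when \code{beta = 0}).
#'
#' For d = 1 with flavor 1 this is preferential attachment on a growing tree
#' and produces a scale-free degree distribution.
#'
#' @param spec A [basal_geometry_spec()].
#' @param n_nodes Total node count; must be at least \code{dimension + 1}.
#' @param seed Integer seed; same seed and spec give an identical graph.
#' @return An undirected \pkg{igraph} graph with \code{n_nodes} vertices.
#' @export
grow_simplicial_complex <- function(spec, n_nodes, seed = 1L) {
  stopifnot(inherits(spec, "basal_geometry_spec"))
  d <- spec$dimension
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < d + 1L)
    stop("n_nodes must be at least dimension + 1 = ", d + 1L)
  n_nodes <- as.integer(n_nodes)
  flavor <- spec$shape_params[1]
  beta <- spec$shape_params[2]

  set.seed(as.integer(seed))
  energy <- sample.int(11L, n_nodes, replace = TRUE) - 1L

  # initial d-simplex on nodes 1..(d+1)
  init <- seq_len(d + 1L)
  edges <- t(utils::combn(init, 2L))
  # (d-1)-faces of the initial simplex, each a d-subset of its nodes
  faces <- if (d == 1L) as.list(init) else
    utils::combn(init, d, simplify = FALSE)
  n_glued <- integer(length(faces))
  face_energy <- vapply(faces, function(f) sum(energy[f]), numeric(1))

  n_steps <- n_nodes - (d + 1L)
  if (n_steps > 0L) {
    edge_buf <- vector("list", n_steps + 1L)
    edge_buf[[1L]] <- edges
    for (step in seq_len(n_steps)) {
      v <- d + 1L + step
      w <- exp(-beta * face_energy) * (1 + flavor * n_glued)
      w[w < 0] <- 0  # saturated faces under flavor = -1
      if (all(w == 0)) stop("all faces saturated; cannot grow further")
      k <- sample.int(length(faces), 1L, prob = w)
      glued <- faces[[k]]
      n_glued[k] <- n_glued[k] + 1L
      edge_buf[[step + 1L]] <- cbind(rep.int(v, d), glued)
      # new (d-1)-faces all contain the new node v
      if (d == 1L) {
        new_faces <- list(v)
      } else {
        drop_one <- utils::combn(glued, d - 1L, simplify = FALSE)
        new_faces <- lapply(drop_one, function(f) c(v, f))
      }
      faces <- c(faces, new_faces)
      n_glued <- c(n_glued, integer(length(new_faces)))
      face_energy <- c(face_energy,
                       vapply(new_faces, function(f) sum(energy[f]),
                              numeric(1)))
    }
    edges <- do.call(rbind, edge_buf)
  }
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Merge basal networks into one geometry
#'
#' Takes the disjoint union of the given graphs and, per merging iteration,
#' adds exactly \code{max(1, round(edge_rate * |V|))} new distinct edges
#' between uniformly random non-adjacent node pairs (collisions with existing
#' or just-added edges are resampled, so the count is exact).
#'
#' @param graphs List of undirected igraph graphs (at least one).
#' @param edge_rate Positive proportionality constant: new edges per node per
#'   iteration.
#' @param iterations Number of merging iterations (0 = plain union).
#' @param seed Integer seed.
#' @return The merged undirected igraph graph; node set is the union.
#' @export
merge_basal_networks <- function(graphs, edge_rate = 0.02, iterations = 1L,
                                 seed = 1L) {
  if (!is.list(graphs) || length(graphs) < 1L ||
      !all(vapply(graphs, igraph::is_igraph, logical(1))))
    stop("graphs must be a nonempty list of igraph graphs")
  if (!is.numeric(edge_rate) || edge_rate <= 0)
    stop("edge_rate must be > 0")
  if (iterations < 0) stop("iterations must be >= 0")

  g <- if (length(graphs) == 1L) graphs[[1L]] else
    do.call(igraph::disjoint_union, graphs)
  nv <- igraph::vcount(g)
  set.seed(as.integer(seed))

  el <- igraph::as_edgelist(g, names = FALSE)
  key <- function(u, v) pmin(u, v) * (nv + 1) + pmax(u, v)
  existing <- new.env(hash = TRUE, size = 4L * nrow(el) + 16L)
  for (i in seq_len(nrow(el)))
    assign(as.character(key(el[i, 1], el[i, 2])), TRUE, envir = existing)
  n_existing <- nrow(el)

  new_edges <- list()
  for (it in seq_len(iterations)) {
    k_new <- max(1L, as.integer(round(edge_rate * nv)))
    n_possible <- nv * (nv - 1) / 2
    if (n_possible - n_existing < k_new)
      stop("graph saturated: requested ", k_new,
           " new edges but only ", n_possible - n_existing, " non-edges left")
    added <- 0L
    while (added < k_new) {
      uv <- sample.int(nv, 2L)
      kk <- as.character(key(uv[1], uv[2]))
      if (exists(kk, envir = existing, inherits = FALSE)) next
      assign(kk, TRUE, envir = existing)
      new_edges[[length(new_edges) + 1L]] <- uv
      added <- added + 1L
      n_existing <- n_existing + 1L
    }
  }
  if (length(new_edges))
    g <- igraph::add_edges(g, as.integer(t(do.call(rbind, new_edges))))
  g
}

#' Construct a regulatory network object
#'
#' Holds the activator and repressor adjacency matrices with the convention
#' that entry \code{(j, i) = 1} means gene j regulates gene i. The full
#' network adjacency is \code{N = A + R}; supports must be disjoint and the
#' diagonal zero (no self-regulation).
#'
#' @param A,R Square binary matrices of equal dimension.
#' @param core_genes Integer indices of core genes (may be empty).
#' @param core_weights Nonnegative weights, one per core gene; default equal
#'   weights \code{1/length(core_genes)}.
#' @return An object of class \code{regulatory_network} with elements
#'   \code{n_genes}, \code{A}, \code{R}, \code{core_genes}, \code{core_weights}.
#' @export
regulatory_network <- function(A, R, core_genes = integer(0),
                               core_weights = NULL) {
  A <- as.matrix(A); R <- as.matrix(R)
  n <- nrow(A)
  if (ncol(A) != n || nrow(R) != n || ncol(R) != n)
    stop("A and R must be square matrices of equal dimension")
  if (!all(A %in% c(0, 1)) || !all(R %in% c(0, 1)))
    stop("A and R must be binary")
  if (any(A * R != 0))
    stop("A and R must have disjoint supports")
  if (any(diag(A) != 0) || any(diag(R) != 0))
    stop("self-regulation (nonzero diagonal) is not allowed")
  core_genes <- as.integer(core_genes)
  if (anyDuplicated(core_genes) || any(core_genes < 1L | core_genes > n))
    stop("core_genes must be unique indices in 1..n_genes")
  if (is.null(core_weights)) {
    core_weights <- if (length(core_genes)) rep(1 / length(core_genes),
                                                length(core_genes)) else numeric(0)
  }
  if (length(core_weights) != length(core_genes) ||
      any(!is.finite(core_weights)) || any(core_weights < 0))
    stop("core_weights must be finite nonnegative, one per core gene")
  structure(
    list(n_genes = n, A = unname(A), R = unname(R),
         core_genes = core_genes, core_weights = as.numeric(core_weights)),
    class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", x$n_genes, "genes,",
      sum(x$A), "activating and", sum(x$R), "repressing edges,",
      length(x$core_genes), "core genes\n")
  invisible(x)
}

#' Full adjacency matrix N = A + R
#' @param network A [regulatory_network()].
#' @return Binary matrix \code{A + R}.
#' @export
network_adjacency <- function(network) network$A + network$R

#' Partition an undirected geometry into activator/repressor subnetworks
#'
#' Each undirected edge \{u, v\} is oriented uniformly at random and labelled
#' activation with probability \code{activation_fraction}, else repression.
#' Every input edge yields exactly one directed entry in A or R.
#'
#' @param graph Undirected igraph graph (no self-loops).
#' @param activation_fraction Probability an edge is activating, in \[0, 1\].
#' @param seed Integer seed.
#' @param core_genes,core_weights Passed to [regulatory_network()].
#' @return A [regulatory_network()].
#' @export
partition_regulators <- function(graph, activation_fraction = 0.5, seed = 1L,
                                 core_genes = integer(0), core_weights = NULL) {
  if (!igraph::is_igraph(graph)) stop("graph must be an igraph graph")
  if (!is.numeric(activation_fraction) || activation_fraction < 0 ||
      activation_fraction > 1)
    stop("activation_fraction must be in [0, 1]")
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (any(el[, 1] == el[, 2])) stop("self-loops are not allowed")
  set.seed(as.integer(seed))
  A <- matrix(0, n, n); R <- matrix(0, n, n)
  if (nrow(el)) {
    flip <- stats::runif(nrow(el)) < 0.5
    from <- ifelse(flip, el[, 2], el[, 1])
    to <- ifelse(flip, el[, 1], el[, 2])
    act <- stats::runif(nrow(el)) < activation_fraction
    A[cbind(from[act], to[act])] <- 1
    R[cbind(from[!act], to[!act])] <- 1
  }
  regulatory_network(A, R, core_genes = core_genes,
                     core_weights = core_weights)
}

#' Generate a complete synthetic regulatory network
#'
#' End-to-end geometry generation: grows up to three basal simplicial
#' complexes (d = 1, 2, 3) sized by their gene fractions, merges them by
#' random-edge insertion, and partitions the result into activator and
#' repressor subnetworks. Basal specs with zero gene fraction are skipped.
#'
#' @param n_genes Total number of genes.
#' @param specs List of [basal_geometry_spec()]s whose gene fractions sum
#'   to 1 (within 1e-9).
#' @param edge_rate,merge_iterations Passed to [merge_basal_networks()].
#' @param activation_fraction Passed to [partition_regulators()].
#' @param core_genes Core gene indices; if \code{NULL}, \code{n_core} genes
#'   are chosen uniformly at random.
#' @param n_core Number of core genes when \code{core_genes} is NULL.
#' @param core_weights Optional weights for the core genes.
#' @param seed Integer master seed.
#' @return A [regulatory_network()].
#' @export
generate_network <- function(n_genes,
                             specs = list(basal_geometry_spec(1L)),
                             edge_rate = 0.02, merge_iterations = 1L,
                             activation_fraction = 0.5,
                             core_genes = NULL, n_core = 0L,
                             core_weights = NULL, seed = 1L) {
  fractions <- vapply(specs, function(s) s$gene_fraction, numeric(1))
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("basal gene fractions must sum to 1")
  active <- which(fractions > 0)
  counts <- round(fractions[active] * n_genes)
  # fix rounding so counts sum to n_genes
  while (sum(counts) != n_genes) {
    i <- which.max(counts)
    counts[i] <- counts[i] + sign(n_genes - sum(counts))
  }
  graphs <- vector("list", length(active))
  for (k in seq_along(active)) {
    sp <- specs[[active[k]]]
    if (counts[k] < sp$dimension + 1L)
      stop("basal network ", k, " would have ", counts[k],
           " nodes, fewer than its minimal simplex size ", sp$dimension + 1L)
    graphs[[k]] <- grow_simplicial_complex(sp, counts[k], seed = seed + k)
  }
  merged <- merge_basal_networks(graphs, edge_rate = edge_rate,
                                 iterations = merge_iterations,
                                 seed = seed + 101L)
  if (is.null(core_genes) && n_core > 0L) {
    set.seed(as.integer(seed) + 202L)
    core_genes <- sort(sample.int(n_genes, n_core))
  }
  partition_regulators(merged, activation_fraction = activation_fraction,
                       seed = seed + 303L,
                       core_genes = core_genes %||% integer(0),
                       core_weights = core_weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a plain-text adjacency matrix
#'
#' Adjacency files are plain text: one row per line, n whitespace-separated
#' 0/1 tokens, n lines. \code{read_adjacency(write_adjacency(x))} is
#' bit-exact.
#'
#' @param matrix Square binary matrix.
#' @param path File path.
#' @export
write_adjacency <- function(matrix, path) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix) || !all(matrix %in% c(0, 1)))
    stop("adjacency must be a square binary matrix")
  writeLines(apply(matrix, 1L, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_adjacency
#' @return \code{read_adjacency}: the parsed integer matrix.
#' @export
read_adjacency <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("empty adjacency file: ", path)
  out <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) != n)
      stop("adjacency parse error at line ", i, ": expected ", n,
           " tokens, found ", length(toks))
    if (!all(toks %in% c("0", "1")))
      stop("adjacency parse error at line ", i, ": non-binary token '",
           toks[which(!toks %in% c("0", "1"))[1L]], "'")
    out[i, ] <- as.integer(toks)
  }
  out
}

#' Write / read the three network files N, A, R
#'
#' @param network A [regulatory_network()].
#' @param prefix Path prefix; files \code{<prefix>.N.grm}, \code{<prefix>.A.grm}
#'   and \code{<prefix>.R.grm} are written.
#' @return \code{write_network}: the three paths, invisibly.
#'   \code{read_network}: a [regulatory_network()] (core genes must be
#'   supplied separately).
#' @export
write_network <- function(network, prefix) {
  paths <- paste0(prefix, c(".N.grm", ".A.grm", ".R.grm"))
  write_adjacency(network_adjacency(network), paths[1L])
  write_adjacency(network$A, paths[2L])
  write_adjacency(network$R, paths[3L])
  invisible(paths)
}

#' @rdname write_network
#' @param core_genes,core_weights Passed to [regulatory_network()].
#' @export
read_network <- function(prefix, core_genes = integer(0),
                         core_weights = NULL) {
  A <- read_adjacency(paste0(prefix, ".A.grm"))
  R <- read_adjacency(paste0(prefix, ".R.grm"))
  regulatory_network(A, R, core_genes = core_genes,
                     core_weights = core_weights)
}

#' Discrete power-law fit of a degree tail
#'
#' Maximum-likelihood fit of the discrete power law
#' \eqn{P(k) = k^{-\alpha} / \zeta(\alpha, x_{min})} to the upper tail of a
#' sample of positive integers, selecting \code{xmin} by minimizing the
#' Kolmogorov-Smirnov distance between the fitted and empirical tail CDFs
#' (Clauset-style). The Hurwitz zeta function is evaluated by truncated
#' summation with an Euler-Maclaurin tail correction.
#'
#' @param x Integer sample (zeros are dropped).
#' @param xmin_candidates Candidate xmin values; default all unique values
#'   with at least 10 tail observations.
#' @return List with \code{alpha}, \code{xmin}, \code{ks}, \code{n_tail},
#'   \code{converged}.
#' @export
fit_powerlaw_discrete <- function(x, xmin_candidates = NULL) {
  x <- as.integer(x[x >= 1L])
  failed <- list(alpha = NA_real_, xmin = NA_integer_, ks = NA_real_,
                 n_tail = 0L, converged = FALSE)
  if (length(x) < 10L || length(unique(x)) < 2L) return(failed)
  if (is.null(xmin_candidates)) {
    u <- sort(unique(x))
    xmin_candidates <- u[vapply(u, function(v) sum(x >= v) >= 10L,
                                logical(1))]
  }
  if (!length(xmin_candidates)) return(failed)
  best <- NULL
  for (xmin in xmin_candidates) {
    tail_x <- x[x >= xmin]
    if (length(unique(tail_x)) < 2L) next
    nll <- function(alpha)
      alpha * sum(log(tail_x)) + length(tail_x) * log(hurwitz_zeta(alpha, xmin))
    opt <- stats::optimize(nll, c(1.01, 8))
    alpha <- opt$minimum
    kmax <- max(tail_x)
    ks_grid <- xmin:kmax
    pk <- ks_grid^(-alpha) / hurwitz_zeta(alpha, xmin)
    cdf_fit <- cumsum(pk)
    cdf_emp <- vapply(ks_grid, function(k) mean(tail_x <= k), numeric(1))
    ks <- max(abs(cdf_fit - cdf_emp))
    if (is.null(best) || ks < best$ks)
      best <- list(alpha = alpha, xmin = as.integer(xmin), ks = ks,
                   n_tail = length(tail_x), converged = TRUE)
  }
  best %||% failed
}

# Hurwitz zeta sum_{k>=a} k^-s by truncated sum + Euler-Maclaurin tail
hurwitz_zeta <- function(s, a, n_terms = 10000L) {
  k <- a:(a + n_terms - 1L)
  K <- a + n_terms
  sum(k^(-s)) + K^(1 - s) / (s - 1) + 0.5 * K^(-s)
}

#' Connectivity report for a regulatory network
#'
#' In- and out-degree histograms over the full adjacency N = A + R plus a
#' discrete power-law MLE fit of each degree tail. A gene's in-degree is its
#' number of regulators; out-degree its number of targets.
#'
#' @param network A [regulatory_network()].
#' @return List of class \code{connectivity_report} with degree vectors,
#'   histograms (named count tables) and the two power-law fits.
#' @export
connectivity_report <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  N <- network_adjacency(network)
  in_deg <- colSums(N)
  out_deg <- rowSums(N)
  structure(
    list(in_degree = in_deg, out_degree = out_deg,
         in_degree_histogram = table(in_deg),
         out_degree_histogram = table(out_deg),
         fit_in = fit_powerlaw_discrete(in_deg),
         fit_out = fit_powerlaw_discrete(out_deg),
         fit_method = "discrete MLE, KS-selected xmin"),
    class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("Connectivity report over", length(x$in_degree), "genes\n")
  cat("  in-degree:  max", max(x$in_degree),
      if (x$fit_in$converged)
        sprintf("; power-law alpha %.2f (xmin %d)", x$fit_in$alpha,
                x$fit_in$xmin) else "; fit not converged", "\n")
  cat("  out-degree: max", max(x$out_degree),
      if (x$fit_out$converged)
        sprintf("; power-law alpha %.2f (xmin %d)", x$fit_out$alpha,
                x$fit_out$xmin) else "; fit not converged", "\n")
  invisible(x)
}
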