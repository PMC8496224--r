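# Simplicial-complex growth, merging, regulator partition, adjacency I/O,
# connectivity statistics.

test_that("growth obeys the d-simplex node/edge identities", {
  for (case in list(list(d = 1L, t = 7L, nodes = 9L, edges = 8L),
                    list(d = 2L, t = 5L, nodes = 8L, edges = 13L),
                    list(d = 1L, t = 0L, nodes = 2L, edges = 1L))) {
    g <- grow_simplicial_complex(basal_geometry_spec(case$d),
                                 case$nodes, seed = 11)
    expect_equal(as.numeric(igraph::vcount(g)), case$nodes)
    expect_equal(as.numeric(igraph::ecount(g)), case$edges)
  }
  # structural identities |E| = d|V| - d(d+1)/2 at larger sizes
  for (d in 1:3) {
    g <- grow_simplicial_complex(basal_geometry_spec(d), 200L, seed = 3)
    expect_equal(as.numeric(igraph::ecount(g)), d * 200 - d * (d + 1) / 2)
    expect_true(igraph::is_connected(g))
  }
})

test_that("growth validates its arguments", {
  expect_error(grow_simplicial_complex(basal_geometry_spec(3L), 3L),
               "at least")
  expect_error(basal_geometry_spec(2L, shape_params = c(1, NaN)), "finite")
  expect_error(basal_geometry_spec(4L), "dimension")
})

test_that("same seed and spec give bit-identical output", {
  s <- basal_geometry_spec(2L, shape_params = c(1, 0.5))
  g1 <- grow_simplicial_complex(s, 80L, seed = 9)
  g2 <- grow_simplicial_complex(s, 80L, seed = 9)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  net1 <- generate_network(40L, n_core = 5L, seed = 13)
  net2 <- generate_network(40L, n_core = 5L, seed = 13)
  expect_identical(net1, net2)
})

test_that("d=1 growth has a heavy, power-law tail", {
  g <- grow_simplicial_complex(basal_geometry_spec(1L), 1000L, seed = 21)
  deg <- igraph::degree(g)
  fit <- fit_powerlaw_discrete(deg)
  expect_true(fit$converged)
  expect_gt(fit$alpha, 1.5)
  expect_lt(fit$alpha, 3.5)
  # heavier tail than an Erdos-Renyi graph of equal |V|, |E|
  set.seed(1)
  er <- igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
  expect_gt(mean(deg >= 10), mean(igraph::degree(er) >= 10))
})

test_that("merging adds exactly the contracted number of distinct edges", {
  gs <- lapply(1:3, function(k)
    grow_simplicial_complex(basal_geometry_spec(1L), 34L, seed = k))
  u0 <- merge_basal_networks(gs, iterations = 0L)
  expect_equal(as.numeric(igraph::ecount(u0)),
               sum(vapply(gs, function(g) as.numeric(igraph::ecount(g)),
                          numeric(1))))
  u1 <- merge_basal_networks(gs, edge_rate = 0.03, iterations = 1L, seed = 5)
  expect_equal(as.numeric(igraph::ecount(u1)),
               as.numeric(igraph::ecount(u0)) + 3)  # round(.03 * 102)
  el <- igraph::as_edgelist(u1, names = FALSE)
  expect_false(any(duplicated(t(apply(el, 1L, sort)))))
  # enough iterations connect the three components (component-count oracle)
  u_many <- merge_basal_networks(gs, edge_rate = 0.05, iterations = 30L,
                                 seed = 6)
  expect_equal(as.numeric(igraph::count_components(u_many)), 1)
})

test_that("merging a saturated graph is an error", {
  full <- igraph::make_full_graph(4)
  expect_error(merge_basal_networks(list(full), edge_rate = 1,
                                    iterations = 1L), "saturated")
})

test_that("partition covers every edge once with disjoint A and R", {
  g <- grow_simplicial_complex(basal_geometry_spec(2L), 60L, seed = 2)
  net <- partition_regulators(g, activation_fraction = 0.4, seed = 8)
  expect_equal(sum(net$A) + sum(net$R), as.numeric(igraph::ecount(g)))
  expect_true(all(net$A * net$R == 0))
  expect_true(all(diag(net$A + net$R) == 0))
  # every undirected edge appears in exactly one direction
  N <- network_adjacency(net)
  expect_true(all(N + t(N) <= 1))
  expect_equal(sum((N + t(N)) > 0) / 2, as.numeric(igraph::ecount(g)))

  all_act <- partition_regulators(g, activation_fraction = 1, seed = 8)
  expect_equal(sum(all_act$R), 0)
  expect_equal(sum(all_act$A), as.numeric(igraph::ecount(g)))
})

test_that("activation labelling is Bernoulli(activation_fraction)", {
  # 400 edges at fraction 0.5: exact 99% binomial interval around 200
  g <- igraph::make_ring(400)
  lo <- qbinom(0.005, 400, 0.5); hi <- qbinom(0.995, 400, 0.5)
  net <- partition_regulators(g, activation_fraction = 0.5, seed = 31)
  expect_gte(sum(net$A), lo)
  expect_lte(sum(net$A), hi)
})

test_that("adjacency files roundtrip bit-exactly and reject bad input", {
  m <- matrix(rbinom(49, 1, 0.3), 7, 7); diag(m) <- 0
  path <- withr::local_tempfile(fileext = ".grm")
  write_adjacency(m, path)
  expect_identical(read_adjacency(path), matrix(as.integer(m), 7, 7))

  writeLines(c("0 1 0", "1 0", "0 0 1"), path)
  expect_error(read_adjacency(path), "line 2")
  writeLines(c("0 2 0", "1 0 0", "0 0 1"), path)
  expect_error(read_adjacency(path), "line 1")
})

test_that("written N, A, R files read back with N = A + R", {
  net <- generate_network(50L, n_core = 12L, seed = 4)
  prefix <- file.path(withr::local_tempdir(), "net")
  write_network(net, prefix)
  N <- read_adjacency(paste0(prefix, ".N.grm"))
  A <- read_adjacency(paste0(prefix, ".A.grm"))
  R <- read_adjacency(paste0(prefix, ".R.grm"))
  expect_identical(N, A + R)
  expect_true(all(A * R == 0))
  back <- read_network(prefix, core_genes = net$core_genes)
  expect_equal(back$A, matrix(as.numeric(net$A), 50, 50))
})

test_that("connectivity report: degrees, conservation and fit recovery", {
  # directed star: hub gene 1 activates 5 leaves
  A <- matrix(0, 6, 6); A[1, 2:6] <- 1
  net <- regulatory_network(A, matrix(0, 6, 6))
  rep <- connectivity_report(net)
  expect_identical(unname(rep$out_degree[1L]), 5)
  expect_true(all(rep$in_degree[2:6] == 1))
  expect_identical(sum(rep$in_degree_histogram), 6L)
  expect_identical(sum(rep$out_degree_histogram), 6L)

  # degenerate all-equal degrees: histograms fine, fit flagged
  ring <- partition_regulators(igraph::make_ring(12), 1, seed = 1)
  rep2 <- connectivity_report(ring)
  expect_false(rep2$fit_in$converged)

  # known ground truth: discrete power law alpha = 2.5, n = 5000
  set.seed(77)
  x <- sample_discrete_powerlaw(5000L, 2.5)
  fit <- fit_powerlaw_discrete(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - 2.5), 0.2)
})
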