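test_that("network construction applies the inclusive threshold rule", {
  sm <- sim_from_pairs(c("A", "B", "C"),
                       list(list("A", "B", 0.9), list("A", "C", 0.7),
                            list("B", "C", 0.3)))
  net <- build_network(sm, st = 0.66)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)
  expect_false(igraph::are_adjacent(net, "B", "C"))
  # boundary |r| == st is an edge ("minimal strength" is inclusive)
  net2 <- build_network(sm, st = 0.7)
  expect_true(igraph::are_adjacent(net2, "A", "C"))
  # isolated nodes are excluded
  net3 <- build_network(sm, st = 0.8)
  expect_setequal(igraph::V(net3)$name, c("A", "B"))
  expect_equal(formals(build_network)$st, 0.66)
  empty <- similarity_matrix(diag(1, 3), otu_ids = c("A", "B", "C"))
  expect_error(build_network(empty, 0.5), "empty")
})

test_that("closed-form fixtures: triangle and 3-node path indices", {
  tri <- graph_fixture(list(c("a", "b"), c("b", "c"), c("a", "c")))
  gi <- global_indices(tri, detect_modules(tri))
  expect_equal(gi$average_degree, 2)
  expect_equal(gi$average_path_distance, 1)
  expect_equal(gi$average_clustering_coefficient, 1)
  expect_equal(gi$average_harmonic_geodesic_distance, 1)

  path <- graph_fixture(list(c("a", "b"), c("b", "c")))
  gp <- global_indices(path, detect_modules(path))
  expect_equal(gp$average_path_distance, 4 / 3)
  expect_equal(gp$average_harmonic_geodesic_distance,
               6 / (1 + 1 + 1 + 1 + 0.5 + 0.5))
  expect_equal(gp$average_clustering_coefficient, 0)
})

test_that("indices agree with brute-force BFS and direct-formula oracles", {
  set.seed(301)
  for (rep in 1:10) {
    n <- sample(10:40, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.08, 0.3))
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    if (igraph::ecount(g) < 2) next
    igraph::E(g)$weight <- 1; igraph::E(g)$sign <- 1
    part <- detect_modules(g)
    gi <- global_indices(g, part)
    a <- adj_of(g)
    o <- oracle_path_indices(a)
    expect_equal(gi$average_path_distance, o$avg_path, tolerance = 1e-12)
    expect_equal(gi$average_harmonic_geodesic_distance, o$harmonic,
                 tolerance = 1e-12)
    expect_equal(gi$average_clustering_coefficient, oracle_clustering(a),
                 tolerance = 1e-12)
    # Table-style identity and internal modularity consistency
    expect_equal(gi$average_degree,
                 2 * gi$total_links / gi$network_size, tolerance = 1e-12)
    expect_equal(part$modularity,
                 igraph::modularity(g, part$membership[igraph::V(g)$name],
                                    weights = rep(1, igraph::ecount(g))),
                 tolerance = 1e-12)
    expect_lte(gi$average_harmonic_geodesic_distance,
               gi$average_path_distance + 1e-12)
  }
})

test_that("power-law fit is exact on a planted power law, undefined when degenerate", {
  # degree frequencies f(k) = 64 k^-2 for k = 1, 2, 4, 8: perfect log-log line
  degs <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  g <- igraph::realize_degseq(degs)
  igraph::V(g)$name <- sprintf("n%03d", seq_along(degs))
  expect_equal(power_law_r2(g), 1, tolerance = 1e-12)

  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- letters[1:10]
  expect_message(r2 <- power_law_r2(ring), "undefined")
  expect_true(is.na(r2))

  # Erdos-Renyi degree distributions are Poisson, not scale-free
  set.seed(302)
  bad_fit <- replicate(50, {
    g <- igraph::sample_gnp(200, 0.05)
    igraph::V(g)$name <- sprintf("n%03d", 1:200)
    power_law_r2(g)
  })
  expect_gte(mean(bad_fit < 0.9, na.rm = TRUE), 0.90)
})

test_that("module detection recovers closed-form and planted partitions", {
  two_tri <- graph_fixture(list(c("a", "b"), c("b", "c"), c("a", "c"),
                                c("x", "y"), c("y", "z"), c("x", "z")))
  p <- detect_modules(two_tri)
  expect_equal(p$n_modules, 2)
  expect_equal(p$modularity, 0.5, tolerance = 1e-12)
  expect_equal(p$modularity, modularity_direct(two_tri, p$membership),
               tolerance = 1e-15)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  p5 <- detect_modules(k5)
  expect_equal(p5$n_modules, 1)
  expect_equal(p5$modularity, 0, tolerance = 1e-12)

  skip_if_not_installed("mclust")
  set.seed(303)
  hits <- 0
  for (s in 1:20) {
    g <- igraph::sample_sbm(60, pref.matrix = matrix(c(0.5, 0.02, 0.02, 0.5), 2),
                            block.sizes = c(30, 30))
    igraph::V(g)$name <- sprintf("n%02d", 1:60)
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    truth <- setNames(rep(1:2, each = 30), sprintf("n%02d", 1:60))
    det <- detect_modules(g)$membership
    ari <- mclust::adjustedRandIndex(det, truth[names(det)])
    hits <- hits + (ari >= 0.9)
  }
  expect_gte(hits, 20 * 0.9)
})

test_that("module composition tallies phyla and signed intra-links", {
  edges <- list(c("f1", "f2"), c("f2", "f3"), c("f3", "f4"), c("f4", "f5"),
                c("f5", "f1"), c("f1", "f3"), c("f2", "f4"), c("f1", "f4"),
                c("f2", "f5"), c("f3", "f5"),
                c("g1", "g2"), c("g2", "g3"), c("g3", "g4"), c("g4", "g1"))
  signs <- c(-1, -1, -1, -1, -1, -1, 1, 1, 1, 1,   1, 1, 1, 1)
  g <- graph_fixture(edges, signs = signs)
  part <- structure(list(
    membership = setNames(c(rep(1L, 5), rep(2L, 4)),
                          c(paste0("f", 1:5), paste0("g", 1:4))),
    n_modules = 2L, modularity = modularity_direct(g, setNames(
      c(rep(1L, 5), rep(2L, 4)), c(paste0("f", 1:5), paste0("g", 1:4))))),
    class = "module_partition")
  tax <- setNames(rep("Bacteria;Firmicutes", 5), paste0("f", 1:5))
  mc <- module_composition(g, part, taxonomy = tax, min_size = 5)
  # module 2 (4 nodes) is below min_size and excluded
  expect_equal(mc$summary$module, 1)
  expect_equal(unname(mc$composition[["1"]]["Firmicutes"]), 5)
  # 6 of 10 intra-module-1 links are planted negative
  expect_equal(mc$summary$negative_ratio, 0.6)
})

test_that("exports write well-formed edge lists and node attributes", {
  tri <- graph_fixture(list(c("a", "b"), c("b", "c"), c("a", "c")),
                       weights = c(0.7, 0.8, 0.9), signs = c(1, -1, 1))
  part <- detect_modules(tri)
  ef <- withr::local_tempfile(fileext = ".tsv")
  nf <- withr::local_tempfile(fileext = ".tsv")
  gf <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(tri, ef)
  write_node_attributes(tri, part, NULL, nf)
  write_graphml(tri, gf)
  el <- read.delim(ef)
  expect_setequal(names(el), c("source", "target", "weight", "sign"))
  expect_equal(nrow(el), 3)
  na <- read.delim(nf)
  expect_equal(sort(na$node), c("a", "b", "c"))
  expect_true(all(na$degree == 2))
  expect_true(file.size(gf) > 0)
  back <- igraph::read_graph(gf, format = "graphml")
  expect_equal(igraph::ecount(back), 3)
})
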