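# Brute-force oracles and fixture builders, independent of the code paths
# they check (BFS by hand, direct formulas, planted constructions).

# small counts table with groups
make_table <- function(values, groups = NULL, taxonomy = NULL) {
  otu_table(values, taxonomy = taxonomy, groups = groups, units = "counts")
}

# symmetric adjacency matrix (0/1) of an igraph object, node-name ordered
adj_of <- function(net) {
  nodes <- sort(igraph::V(net)$name)
  a <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  el <- igraph::as_edgelist(net, names = TRUE)
  for (i in seq_len(nrow(el))) {
    a[el[i, 1], el[i, 2]] <- 1L
    a[el[i, 2], el[i, 1]] <- 1L
  }
  a
}

# all-pairs shortest path lengths by hand-rolled BFS on an adjacency matrix
bfs_all_pairs <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  diag(d) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(a[v, ] == 1L & !is.finite(dist))
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
  }
  d
}

# oracle versions of the distance-based indices from a BFS matrix
oracle_path_indices <- function(a) {
  d <- bfs_all_pairs(a)
  up <- d[upper.tri(d)]
  inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  n <- nrow(a)
  list(avg_path = mean(up[is.finite(up)]),
       harmonic = n * (n - 1) / sum(inv))
}

# oracle local clustering coefficient from the adjacency matrix
oracle_clustering <- function(a) {
  n <- nrow(a)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1L)
    k <- length(nb)
    cc[i] <- if (k < 2) 0 else sum(a[nb, nb]) / 2 / (k * (k - 1) / 2)
  }
  mean(cc)
}

# similarity matrix with planted diagonal blocks: within-block |r| drawn
# U(0.75, 0.95), between-block U(0, 0.4); random signs
planted_block_sim <- function(seed, n_blocks = 5, bsize = 30) {
  set.seed(seed)
  n <- n_blocks * bsize
  memb <- rep(seq_len(n_blocks), each = bsize)
  s <- matrix(0, n, n)
  ut <- upper.tri(s)
  same <- outer(memb, memb, "==")
  s[ut & same] <- stats::runif(sum(ut & same), 0.75, 0.95)
  s[ut & !same] <- stats::runif(sum(ut & !same), 0, 0.4)
  s <- s + t(s)
  diag(s) <- 1
  sg <- matrix(sample(c(-1, 1), n * n, replace = TRUE), n)
  sg[lower.tri(sg)] <- t(sg)[lower.tri(sg)]
  diag(sg) <- 1
  rownames(s) <- colnames(s) <- sprintf("OTU%03d", seq_len(n))
  similarity_matrix(s, sg)
}

# tiny similarity matrix from explicit upper-triangle values
sim_from_pairs <- function(ids, pairs) {
  n <- length(ids)
  s <- diag(1, n); dimnames(s) <- list(ids, ids)
  sg <- matrix(1, n, n, dimnames = list(ids, ids))
  for (p in pairs) {
    s[p[[1]], p[[2]]] <- s[p[[2]], p[[1]]] <- p[[3]]
    if (length(p) >= 4) sg[p[[1]], p[[2]]] <- sg[p[[2]], p[[1]]] <- p[[4]]
  }
  similarity_matrix(s, sg)
}

# graph from an explicit edge list with optional weights/signs
graph_fixture <- function(edges, weights = NULL, signs = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = vapply(edges, `[[`, "", 1),
               to = vapply(edges, `[[`, "", 2)),
    directed = FALSE)
  igraph::E(g)$weight <- if (is.null(weights)) rep(1, length(edges)) else weights
  igraph::E(g)$sign <- if (is.null(signs)) rep(1, length(edges)) else signs
  g
}

# end-to-end run on the strong-signal planted study (one group, 40 samples)
run_planted_study <- function(seed) {
  spec <- synthetic_spec(groups = "G1", samples_per_group = 40, n_otu = 152,
                         module_sizes = rep(30, 5), n_brokers = 2, seed = seed)
  gen <- generate_table(spec)
  tab <- relative_abundance(prevalence_filter(rarefy(gen$table, seed = seed),
                                              "G1"))
  smat <- pearson_similarity(tab)
  scan <- scan_threshold(smat)
  net <- build_network(smat, st = scan$st)
  part <- detect_modules(net)
  list(gen = gen, table = tab, scan = scan, net = net, part = part,
       indices = global_indices(net, part))
}
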