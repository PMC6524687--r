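#' Degree-preserving rewiring of a network (Maslov-Sneppen null model)
#'
#' Repeated double-edge swaps: two edges (a,b) and (c,d) are replaced by
#' (a,d) and (c,b), rejecting any swap that would create a self-loop or a
#' duplicate edge.  Every node keeps its exact degree, so the randomised
#' graphs share the empirical network's size and degree distribution but
#' lose its specific wiring.  Graphs admitting no valid swap (e.g. a
#' triangle) are returned unchanged.
#'
#' @param net An \code{igraph} network.
#' @param swaps_per_edge Swap attempts per edge (default 10).
#' @param seed Optional integer seed for reproducibility.
#' @return A rewired \code{igraph} graph with the same degree sequence.
#' @export
rewire_network <- function(net, swaps_per_edge = 10, seed = NULL) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) < 2) return(net)
  if (!is.null(seed)) set.seed(seed)
  niter <- swaps_per_edge * igraph::ecount(net)
  igraph::rewire(net, igraph::keeping_degseq(loops = FALSE, niter = niter))
}

#' Null ensemble of topology indices over random networks
#'
#' Generates \code{n} degree-preserving randomisations of the network and
#' recomputes, for each, the four indices whose significance the null model
#' assesses: average path distance, average clustering coefficient, average
#' harmonic geodesic distance, and modularity (greedy optimisation, same
#' operator as on the empirical network).  Per-member seeds are derived from
#' the master seed by a counter so members are independent and the ensemble
#' is reproducible.
#'
#' @param net An \code{igraph} network.
#' @param n Ensemble size (default 100).
#' @param seed Master seed.
#' @param swaps_per_edge Swap attempts per edge for each member.
#' @return Object of class \code{"null_ensemble"}: list with \code{values}
#'   (n x 4 data frame), \code{mean}, \code{sd} (sample SD, n - 1), and
#'   \code{n}.
#' @export
ensemble_indices <- function(net, n = 100, seed = 1, swaps_per_edge = 10) {
  if (n < 2) stop("ensemble size must be at least 2")
  idx <- c("average_path_distance", "average_clustering_coefficient",
           "average_harmonic_geodesic_distance", "modularity")
  vals <- matrix(NA_real_, n, length(idx), dimnames = list(NULL, idx))
  for (i in seq_len(n)) {
    g <- rewire_network(net, swaps_per_edge = swaps_per_edge,
                        seed = (seed + i) %% .Machine$integer.max)
    gi <- global_indices(g, detect_modules(g))
    vals[i, ] <- as.numeric(gi[1, idx])
  }
  vals <- as.data.frame(vals)
  structure(list(values = vals,
                 mean = colMeans(vals),
                 sd = apply(vals, 2, stats::sd),
                 n = n),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d random networks\n", x$n))
  for (k in names(x$mean))
    cat(sprintf("  %-36s %.3f +/- %.3f\n", k, x$mean[k], x$sd[k]))
  invisible(x)
}

#' Compare an index between two networks via their null-ensemble spreads
#'
#' Student t comparison of one empirical index value per network, using the
#' standard deviations of the corresponding random-network ensembles as the
#' dispersion estimates:
#' t = (a - b) / sqrt(s_a^2/n_a + s_b^2/n_b), with a two-sided p-value on
#' Welch-Satterthwaite degrees of freedom (pooled df is also reported).
#' When both ensemble SDs are zero the comparison is degenerate: p is 0 if
#' the indices differ and 1 if they agree, and the result is flagged.
#'
#' @param index_a,index_b Empirical index values for the two networks.
#' @param ens_a,ens_b Their [ensemble_indices] results.
#' @param index Name of the index column in the ensembles.
#' @return List with \code{t}, \code{df} (Welch), \code{df_pooled},
#'   \code{p_value} and \code{degenerate}.
#' @export
compare_networks <- function(index_a, ens_a, index_b, ens_b,
                             index = "modularity") {
  stopifnot(inherits(ens_a, "null_ensemble"), inherits(ens_b, "null_ensemble"))
  if (!index %in% names(ens_a$mean) || !index %in% names(ens_b$mean))
    stop("unknown index: ", index)
  sa <- ens_a$sd[[index]]; sb <- ens_b$sd[[index]]
  na <- ens_a$n; nb <- ens_b$n
  if (sa == 0 && sb == 0) {
    return(list(t = NA_real_, df = NA_real_, df_pooled = na + nb - 2,
                p_value = if (index_a == index_b) 1 else 0,
                degenerate = TRUE))
  }
  se <- sqrt(sa^2 / na + sb^2 / nb)
  t_stat <- (index_a - index_b) / se
  df_w <- se^4 / ((sa^2 / na)^2 / (na - 1) + (sb^2 / nb)^2 / (nb - 1))
  list(t = t_stat, df = df_w, df_pooled = na + nb - 2,
       p_value = 2 * stats::pt(abs(t_stat), df_w, lower.tail = FALSE),
       degenerate = FALSE)
}
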