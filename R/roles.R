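#' Within-module degree z-score (Zi)
#'
#' Zi measures how strongly a node is connected inside its own module:
#' zi = (k_i - mean(k)) / sd(k), where k_i counts the node's links to other
#' members of its module and the mean and standard deviation (population
#' form) are taken over the module.  Modules in which every member has the
#' same intra-module degree (cliques, singletons) get zi = 0 for all
#' members.
#'
#' @param net An \code{igraph} network.
#' @param partition A [detect_modules] result covering all nodes.
#' @return Named numeric vector of zi values.
#' @export
within_module_z <- function(net, partition) {
  memb <- partition$membership
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(memb)))
    stop("partition does not cover every network node")
  kappa <- intra_module_degree(net, memb)
  zi <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in unique(memb)) {
    members <- names(memb)[memb == s]
    k <- kappa[members]
    mu <- mean(k)
    sd_pop <- sqrt(mean((k - mu)^2))
    zi[members] <- if (sd_pop > 0) (k - mu) / sd_pop else 0
  }
  zi
}

# links of each node to nodes of its own module
intra_module_degree <- function(net, memb) {
  el <- igraph::as_edgelist(net, names = TRUE)
  same <- memb[el[, 1]] == memb[el[, 2]]
  nodes <- igraph::V(net)$name
  kappa <- stats::setNames(numeric(length(nodes)), nodes)
  ends <- c(el[same, 1], el[same, 2])
  if (length(ends)) {
    tab <- table(ends)
    kappa[names(tab)] <- as.numeric(tab)
  }
  kappa
}

#' Among-module participation coefficient (Pi)
#'
#' Pi measures how evenly a node's links are spread over modules:
#' pi = 1 - sum_s (k_is / k_i)^2, with k_is the node's links into module s
#' and k_i its total degree.  A node whose links all stay inside one module
#' has pi = 0; a node spreading evenly over m modules approaches 1 - 1/m.
#'
#' @param net An \code{igraph} network.
#' @param partition A [detect_modules] result covering all nodes.
#' @return Named numeric vector of pi values in [0, 1].
#' @export
participation <- function(net, partition) {
  memb <- partition$membership
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(memb)))
    stop("partition does not cover every network node")
  el <- igraph::as_edgelist(net, names = TRUE)
  pi_v <- stats::setNames(numeric(length(nodes)), nodes)
  # per-node counts of links into each module
  tallies <- list()
  add <- function(node, mod) {
    key <- node
    t <- tallies[[key]]
    if (is.null(t)) t <- integer(0)
    t[as.character(mod)] <- if (is.na(t[as.character(mod)])) 1L else
      t[as.character(mod)] + 1L
    tallies[[key]] <<- t
  }
  for (i in seq_len(nrow(el))) {
    add(el[i, 1], memb[el[i, 2]])
    add(el[i, 2], memb[el[i, 1]])
  }
  for (v in names(tallies)) {
    k_is <- tallies[[v]]
    k <- sum(k_is)
    pi_v[v] <- 1 - sum((k_is / k)^2)
  }
  pi_v
}

#' Classify nodes by their (Zi, Pi) topological role
#'
#' The standard four-way partition of the Z-P plane: module hubs have
#' Pi <= 0.62 and Zi > 2.5, connectors Pi > 0.62 and Zi <= 2.5, network
#' hubs Pi > 0.62 and Zi > 2.5, and peripherals Pi <= 0.62 and Zi <= 2.5.
#' Both boundaries belong to the "<=" side.  Ecologically, peripherals act
#' as specialists, module hubs and connectors as generalists (the putative
#' keystone taxa), and network hubs as super-generalists.
#'
#' @param zi Numeric vector of within-module degree z-scores.
#' @param pi Numeric vector of participation coefficients.
#' @param zi_cut,pi_cut Role thresholds (defaults 2.5 and 0.62).
#' @return Character vector in \{"peripheral", "connector", "module hub",
#'   "network hub"\}.
#' @export
classify_role <- function(zi, pi, zi_cut = 2.5, pi_cut = 0.62) {
  if (length(zi) != length(pi)) stop("'zi' and 'pi' lengths differ")
  out <- ifelse(zi > zi_cut,
                ifelse(pi > pi_cut, "network hub", "module hub"),
                ifelse(pi > pi_cut, "connector", "peripheral"))
  if (!is.null(names(zi))) names(out) <- names(zi)
  out
}

#' Z-P table: per-node role classification for keystone identification
#'
#' One row per node with its module, Zi, Pi, role category and phylum,
#' the data behind a Z-P scatter plot.  Module hubs, network hubs and
#' connectors are flagged as putative keystone taxa.
#'
#' @param net An \code{igraph} network.
#' @param partition A [detect_modules] result.
#' @param taxonomy Optional lineage map.
#' @return Data frame with columns node, module, zi, pi, category, keystone,
#'   phylum.
#' @export
zp_table <- function(net, partition, taxonomy = NULL) {
  zi <- within_module_z(net, partition)
  pi_v <- participation(net, partition)
  nodes <- igraph::V(net)$name
  cat_v <- classify_role(zi[nodes], pi_v[nodes])
  data.frame(node = nodes,
             module = partition$membership[nodes],
             zi = zi[nodes],
             pi = pi_v[nodes],
             category = unname(cat_v),
             keystone = unname(cat_v != "peripheral"),
             phylum = otu_phylum(taxonomy, nodes),
             row.names = NULL)
}
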