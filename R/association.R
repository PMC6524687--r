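#' Signed OTU degree
#'
#' The OTU degree is the sum of the strengths (|r| edge weights) of a node's
#' links to all its connected partners; restricting to positive or negative
#' links gives the signed variants used when relating network wiring to
#' clinical variables.  Count mode counts links instead of summing weights.
#'
#' @param net An \code{igraph} network with \code{weight} and \code{sign}
#'   edge attributes.
#' @param sign_filter \code{"all"}, \code{"positive"} or \code{"negative"}.
#' @param mode \code{"strength"} (default, sum of |r|) or \code{"count"}.
#' @return Named numeric vector over all network nodes (zero where no edge
#'   passes the filter).
#' @export
otu_degree <- function(net, sign_filter = c("all", "positive", "negative"),
                       mode = c("strength", "count")) {
  sign_filter <- match.arg(sign_filter)
  mode <- match.arg(mode)
  stopifnot(igraph::is_igraph(net))
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- igraph::edge_attr(net, "weight")
  s <- igraph::edge_attr(net, "sign")
  if (is.null(w)) w <- rep(1, nrow(el))
  if (is.null(s)) s <- rep(1, nrow(el))
  keep <- switch(sign_filter, all = rep(TRUE, nrow(el)),
                 positive = s > 0, negative = s < 0)
  contrib <- if (mode == "strength") w[keep] else rep(1, sum(keep))
  out <- stats::setNames(numeric(length(nodes)), nodes)
  ends <- c(el[keep, 1], el[keep, 2])
  vals <- c(contrib, contrib)
  if (length(ends)) {
    agg <- tapply(vals, ends, sum)
    out[names(agg)] <- as.numeric(agg)
  }
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-rank (average-rank) Spearman correlation on pairwise-complete
#' observations, with a two-sided p-value from the t approximation on n - 2
#' degrees of freedom.  If either variable has zero rank variance the
#' correlation is undefined and NA is returned for rho and p.
#'
#' @param x,y Numeric vectors of equal length (NAs allowed; pairwise
#'   complete cases are used).
#' @return List with \code{rho}, \code{p_value} and \code{n}.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(t_stat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Degree-by-marker Spearman association grid
#'
#' Correlates per-unit summaries of the three degree variants (all links,
#' negative links, positive links) with per-unit tumour-marker summaries,
#' producing the 4-marker x 3-variant grid used to relate network structure
#' to clinical variables.  The sampling unit is whatever the caller
#' summarised over (typically treatment groups).
#'
#' @param degree_summary Data frame, one row per unit, with columns
#'   \code{all}, \code{negative}, \code{positive} (mean signed OTU degrees).
#' @param marker_summary Data frame, one row per unit (same order), one
#'   column per marker (e.g. CA242, CEA, CA199, CA724).
#' @return Data frame with columns marker, degree_variant, rho, p_value, n.
#' @export
degree_marker_table <- function(degree_summary, marker_summary) {
  need <- c("all", "negative", "positive")
  if (!all(need %in% names(degree_summary)))
    stop("degree_summary needs columns: ", paste(need, collapse = ", "))
  if (nrow(degree_summary) != nrow(marker_summary))
    stop("degree and marker summaries must have the same number of units")
  if (nrow(degree_summary) < 3)
    stop("need at least 3 units for a Spearman correlation")
  rows <- list()
  for (m in names(marker_summary)) {
    for (v in need) {
      res <- tryCatch(spearman_assoc(degree_summary[[v]], marker_summary[[m]]),
                      error = function(e) list(rho = NA_real_,
                                               p_value = NA_real_, n = NA))
      rows[[paste(m, v)]] <- data.frame(marker = m, degree_variant = v,
                                        rho = res$rho, p_value = res$p_value,
                                        n = res$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keystone OTU abundance versus tumour markers
#'
#' Spearman correlation of each keystone OTU's relative abundance with each
#' tumour marker across the samples where both are observed.
#'
#' @param x An [otu_table] (relative abundances in the standard pipeline).
#' @param keystones Character vector of OTU ids; all must be present.
#' @param markers Data frame of marker values, row names = sample ids,
#'   one column per marker.
#' @return Data frame with columns otu, marker, rho, p_value, n.
#' @export
keystone_marker_association <- function(x, keystones, markers) {
  stopifnot(inherits(x, "otu_table"))
  missing <- setdiff(keystones, rownames(x$values))
  if (length(missing))
    stop("keystone OTU(s) absent from the table: ",
         paste(missing, collapse = ", "))
  shared <- intersect(colnames(x$values), rownames(markers))
  if (length(shared) < 3)
    stop("fewer than 3 samples shared between table and markers")
  rows <- list()
  for (otu in keystones) {
    ab <- x$values[otu, shared]
    for (m in names(markers)) {
      res <- tryCatch(spearman_assoc(ab, markers[shared, m]),
                      error = function(e) list(rho = NA_real_,
                                               p_value = NA_real_, n = NA))
      rows[[paste(otu, m)]] <- data.frame(otu = otu, marker = m,
                                          rho = res$rho,
                                          p_value = res$p_value, n = res$n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
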