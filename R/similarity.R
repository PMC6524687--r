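#' Absolute Pearson similarity matrix with retained signs
#'
#' Correlates every pair of OTU abundance profiles across samples and stores
#' the magnitude and the sign separately: the magnitude matrix \code{sim}
#' holds |r| (this is what the similarity threshold is applied to), and
#' \code{sign} records whether the underlying correlation was positive
#' (co-occurrence) or negative (co-exclusion).
#'
#' OTU rows with zero variance across samples carry no correlation signal
#' and are dropped with a warning before computing the matrix.
#'
#' @param x An [otu_table] with at least 3 samples (relative abundances in
#'   the standard pipeline, but any units are accepted).
#' @return An object of class \code{"similarity_matrix"}: a list with
#'   \code{otu_ids}, \code{sim} (symmetric |r|, unit diagonal) and
#'   \code{sign} (matrix in \{-1, 0, +1\}).
#' @export
pearson_similarity <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (ncol(x$values) < 3)
    stop("at least 3 samples are required for Pearson correlation")
  v <- x$values
  sds <- apply(v, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning(sprintf("dropping %d zero-variance OTU row(s)", sum(flat)))
    v <- v[!flat, , drop = FALSE]
  }
  if (nrow(v) < 2) stop("fewer than 2 OTUs with non-zero variance")
  r <- stats::cor(t(v))
  diag(r) <- 1
  similarity_matrix(abs(r), sign(r), rownames(v))
}

#' Assemble a similarity matrix object
#'
#' @param sim Symmetric matrix of |r| values in [0, 1] with unit diagonal.
#' @param sign Symmetric matrix of correlation signs in \{-1, 0, 1\}.
#' @param otu_ids Node identifiers (defaults to the row names of \code{sim}).
#' @return A \code{"similarity_matrix"} object.
#' @export
similarity_matrix <- function(sim, sign = NULL, otu_ids = rownames(sim)) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim))
    stop("'sim' must be a square matrix")
  if (is.null(otu_ids)) stop("OTU ids are required")
  if (max(abs(sim - t(sim))) > 1e-12) stop("'sim' must be symmetric")
  if (any(sim < -1e-12) || any(sim > 1 + 1e-12))
    stop("'sim' entries must lie in [0, 1]")
  if (any(abs(diag(sim) - 1) > 1e-12)) stop("'sim' must have unit diagonal")
  if (is.null(sign)) sign <- matrix(1, nrow(sim), ncol(sim))
  if (!all(sign %in% c(-1, 0, 1))) stop("'sign' entries must be -1, 0 or 1")
  dimnames(sim) <- list(otu_ids, otu_ids)
  dimnames(sign) <- list(otu_ids, otu_ids)
  structure(list(otu_ids = otu_ids, sim = sim, sign = sign),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$sim[upper.tri(x$sim)]
  cat(sprintf("similarity_matrix: %d OTUs; off-diagonal |r| median %.3f, max %.3f\n",
              length(x$otu_ids), stats::median(off), max(off)))
  invisible(x)
}
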