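#' Unfold an eigenvalue spectrum to unit mean level spacing
#'
#' Spectral unfolding rescales eigenvalues so the local mean spacing is one
#' everywhere, which makes nearest-neighbour spacing distributions comparable
#' with the universal laws (Poisson, Wigner/GOE).  The unfolded levels are
#' e_i = N * F(lambda_i), where F is a smooth monotone (Hyman-filtered cubic
#' spline) fit to the empirical cumulative spectral function evaluated at a
#' subset of knot eigenvalues.
#'
#' Near-degenerate eigenvalues (consecutive gap < 1e-10) are collapsed to a
#' single representative before unfolding: exact degeneracies carry no
#' spacing information and would otherwise pin the spacing histogram at zero.
#'
#' The knot density trades smoothness against fidelity to the spectral
#' density: too few knots under-fit composite densities (e.g. superposed
#' module spectra) and the resulting systematic spacing distortion masquerades
#' as a deviation from the Poisson law, while the default
#' \code{ceiling(N/8)} tracks such densities without absorbing the local
#' level fluctuations the spacing test must retain (exponential-spacing
#' calibration and GOE rejection are both preserved; see the methods
#' vignette).
#'
#' @param eigenvalues Numeric vector of eigenvalues (any order).
#' @param knots Number of spline knots; default \code{max(5, ceiling(N/8))}
#'   where N is the number of distinct eigenvalues.
#' @return Non-decreasing numeric vector of unfolded eigenvalues with mean
#'   nearest-neighbour spacing 1 (up to spline fit error).
#' @export
unfold_spectrum <- function(eigenvalues, knots = NULL) {
  ev <- sort(as.numeric(eigenvalues))
  if (length(ev) >= 2) {
    keep <- c(TRUE, diff(ev) >= 1e-10)   # collapse near-degenerate levels
    ev <- ev[keep]
  }
  n <- length(ev)
  if (n < 30)
    stop("too few distinct eigenvalues (", n,
         " < 30) for spectral unfolding; stop the threshold scan")
  if (is.null(knots)) knots <- max(5L, ceiling(n / 8))
  knots <- max(3L, min(as.integer(knots), n))
  # empirical cumulative spectral function at each level
  F_emp <- seq_len(n) / n
  ki <- unique(round(seq(1, n, length.out = knots)))
  fit <- stats::splinefun(ev[ki], F_emp[ki], method = "hyman")
  e <- n * pmin(pmax(fit(ev), 0), 1)
  cummax(e)   # enforce monotonicity against numerical wiggle
}

#' Chi-square goodness of fit of a spacing distribution to Poisson or GOE
#'
#' Bins the nearest-neighbour spacings of an unfolded spectrum on
#' \code{[0, range_max]} and compares the histogram with the expected mass
#' under the exponential law P(d) = exp(-d) (Poisson statistics: modular,
#' non-random system) or the Wigner surmise
#' P(d) = (pi d / 2) exp(-pi d^2 / 4) (GOE statistics: random system).
#'
#' Expected masses are renormalised over \code{[0, range_max]} and adjacent
#' bins are pooled left to right until each pooled bin has expected count at
#' least \code{min_expected}, the usual validity condition for the chi-square
#' approximation; degrees of freedom are (pooled bins - 1).
#'
#' @param unfolded Unfolded eigenvalues from [unfold_spectrum].
#' @param law \code{"poisson"} or \code{"goe"}.
#' @param bin_width Histogram bin width in units of mean spacing.
#' @param range_max Upper end of the binned spacing range.
#' @param min_expected Minimum expected count per pooled bin.
#' @return List with \code{statistic}, \code{df}, \code{p_value}, and
#'   \code{n_spacings} used.
#' @export
nnsd_chi_square <- function(unfolded, law = c("poisson", "goe"),
                            bin_width = 0.1, range_max = 3.0,
                            min_expected = 5) {
  law <- match.arg(law)
  d <- diff(sort(as.numeric(unfolded)))
  if (length(d) == 0) stop("empty spacing set")
  d_in <- d[d <= range_max]
  n <- length(d_in)
  if (n == 0) stop("no spacings within [0, range_max]")
  breaks <- seq(0, range_max, by = bin_width)
  obs <- graphics::hist(d_in, breaks = breaks, plot = FALSE)$counts
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  mass <- switch(law,
    poisson = exp(-lo) - exp(-hi),
    goe     = exp(-pi * lo^2 / 4) - exp(-pi * hi^2 / 4)
  )
  mass <- mass / sum(mass)          # renormalise over the binned range
  expd <- n * mass
  # pool adjacent bins until each pooled expected count reaches min_expected
  po <- pe <- numeric(0)
  acc_o <- acc_e <- 0
  for (j in seq_along(expd)) {
    acc_o <- acc_o + obs[j]
    acc_e <- acc_e + expd[j]
    if (acc_e >= min_expected) {
      po <- c(po, acc_o); pe <- c(pe, acc_e)
      acc_o <- acc_e <- 0
    }
  }
  if (acc_e > 0) {                  # fold the remainder into the last pool
    if (length(pe) == 0) { po <- acc_o; pe <- acc_e }
    else {
      po[length(po)] <- po[length(po)] + acc_o
      pe[length(pe)] <- pe[length(pe)] + acc_e
    }
  }
  stat <- sum((po - pe)^2 / pe)
  df <- max(1L, length(pe) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       n_spacings = n)
}

#' Scan similarity thresholds and choose St by RMT spacing statistics
#'
#' Walks an ascending grid of candidate similarity thresholds.  At each
#' candidate s the similarity matrix is pruned (entries with |r| < s zeroed,
#' rows/columns left without any off-diagonal survivor removed), the
#' eigenvalues of the pruned weighted matrix are unfolded, and the
#' nearest-neighbour spacing distribution is tested against the Poisson and
#' GOE laws.  Below the transition the spectrum behaves like a random (GOE)
#' system; once the threshold isolates the modular signal the spacings turn
#' Poisson.  The chosen threshold St is the smallest grid value whose
#' Poisson p-value exceeds \code{alpha} and stays above \code{alpha} for the
#' next \code{stability} grid points (guarding against single-point noise
#' acceptances).
#'
#' @param smat A [similarity_matrix].
#' @param grid_start,grid_end,grid_step Threshold grid (default 0.30 to 0.99
#'   in steps of 0.01).
#' @param alpha Significance level for Poisson non-rejection.
#' @param stability Number of subsequent grid points that must also be
#'   non-rejected (default 2).
#' @param min_order Scan stops when the pruned matrix order drops below this.
#' @return An object of class \code{"threshold_scan"}: list with \code{st}
#'   (chosen threshold) and \code{trace} (data frame: threshold, order,
#'   chi2_poisson, p_poisson, chi2_goe, p_goe, accepted).
#' @export
scan_threshold <- function(smat, grid_start = 0.30, grid_end = 0.99,
                           grid_step = 0.01, alpha = 0.05,
                           stability = 2, min_order = 30) {
  stopifnot(inherits(smat, "similarity_matrix"))
  grid <- seq(grid_start, grid_end, by = grid_step)
  rows <- vector("list", length(grid))
  n_done <- 0
  for (i in seq_along(grid)) {
    s <- grid[i]
    a <- smat$sim
    a[a < s] <- 0
    diag(a) <- 1
    deg <- rowSums(a > 0) - 1          # off-diagonal survivors
    keep <- deg > 0
    ord <- sum(keep)
    if (ord < min_order) break
    a <- a[keep, keep, drop = FALSE]
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    unf <- tryCatch(unfold_spectrum(ev), error = function(e) NULL)
    if (is.null(unf)) break            # too few distinct levels: stop scan
    poi <- nnsd_chi_square(unf, "poisson")
    goe <- nnsd_chi_square(unf, "goe")
    rows[[i]] <- data.frame(threshold = s, order = ord,
                            chi2_poisson = poi$statistic,
                            p_poisson = poi$p_value,
                            chi2_goe = goe$statistic,
                            p_goe = goe$p_value,
                            accepted = FALSE)
    n_done <- i
  }
  if (n_done == 0)
    stop("threshold scan degenerate: no grid point yields a matrix of order >= ",
         min_order)
  trace <- do.call(rbind, rows[seq_len(n_done)])
  ok <- trace$p_poisson > alpha
  chosen <- NA_real_
  for (i in seq_len(n_done)) {
    if (i + stability > n_done) break
    if (all(ok[i:(i + stability)])) { chosen <- trace$threshold[i]; break }
  }
  if (is.na(chosen)) {
    msg <- paste(utils::capture.output(print(utils::head(trace, 20))),
                 collapse = "\n")
    stop("no threshold accepted by the Poisson stability rule before the ",
         "matrix shrank below order ", min_order, "; scan trace:\n", msg)
  }
  trace$accepted <- trace$threshold >= chosen & ok
  structure(list(st = chosen, trace = trace), class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("threshold_scan: %d grid points, chosen St = %.3f\n",
              nrow(x$trace), x$st))
  invisible(x)
}

#' Write a threshold scan trace as TSV
#'
#' @param x A \code{"threshold_scan"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_scan_trace <- function(x, path) {
  stopifnot(inherits(x, "threshold_scan"))
  utils::write.table(x$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
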