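#' Specification for a synthetic group-structured OTU study
#'
#' Describes a simulated study shaped like a multi-group 16S survey: several
#' groups of samples (default seven groups of 21, a healthy group plus six
#' treatment stages), a few hundred OTUs, a planted modular signed
#' correlation structure among a subset of OTUs, optional cross-module
#' "broker" OTUs (planted connector candidates), and sequencing-style
#' integer counts at a target library depth.
#'
#' The latent correlation model is an exact block-structured multivariate
#' normal realised through a factor construction: module members load on a
#' shared module factor (within-module correlation \code{rho_w}), module
#' factors share a background factor (between-module correlation
#' \code{rho_b}), background OTUs load weakly on the background factor, and
#' a fraction of module members are axis-reflected (latent sign flip) so
#' that within-module couplings split into co-occurrence and co-exclusion
#' with negative fraction about \code{f_neg}.
#'
#' @param groups Character vector of group labels.
#' @param samples_per_group Samples per group (default 21).
#' @param n_otu Total OTU count (default 800).
#' @param module_sizes Integer vector of planted module sizes (default five
#'   modules of 30); remaining OTUs are unstructured background.
#' @param rho_w Latent within-module correlation (default 0.85).
#' @param rho_b Latent between-module / background correlation (default 0.1);
#'   must be smaller than \code{rho_w} (both may be 0 for a null table).
#' @param f_neg Target fraction of negative within-module couplings
#'   (default 0.45; axis reflection can realise at most ~0.5).
#' @param n_brokers Number of broker OTUs loading evenly on four
#'   consecutive modules (default 2; requires at least 4 modules when > 0).
#'   Four-way spreading keeps a broker's participation coefficient ceiling
#'   (0.75) well above the 0.62 connector cut-off; an evenly spread
#'   three-way broker caps at 2/3 and sampling noise straddles the cut-off.
#' @param meanlog,sdlog_between Lognormal baseline abundance across OTUs.
#' @param sdlog_within Log-scale dispersion of each OTU across samples
#'   (default 0.35, small enough that the exponential link preserves the
#'   planted Pearson structure).
#' @param zero_inflation Probability that any abundance is replaced by a
#'   structural zero (default 0).
#' @param depth Target library size per sample (default 41000 so columns
#'   comfortably exceed the standard rarefaction depth of 39796).
#' @param seed Master seed.
#' @return Object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(groups = c("H", paste0("T", 0:5)),
                           samples_per_group = 21,
                           n_otu = 800,
                           module_sizes = rep(30L, 5),
                           rho_w = 0.85, rho_b = 0.1, f_neg = 0.45,
                           n_brokers = 2,
                           meanlog = 0, sdlog_between = 1,
                           sdlog_within = 0.35,
                           zero_inflation = 0,
                           depth = 41000,
                           seed = 1) {
  if (rho_w < 0 || rho_w > 1 || rho_b < 0 || rho_b > rho_w ||
      (rho_w > 0 && rho_b >= rho_w))
    stop("need 0 <= rho_b < rho_w <= 1 (or both 0 for a null table): the ",
         "factor construction requires a positive-definite block ",
         "correlation; lower rho_b or raise rho_w)")
  if (f_neg < 0 || f_neg > 0.5)
    stop("'f_neg' must lie in [0, 0.5]: axis reflection cannot make more ",
         "than half of within-module couplings negative")
  if (sum(module_sizes) + n_brokers > n_otu)
    stop("module sizes plus brokers exceed the OTU count")
  if (n_brokers > 0 && length(module_sizes) < 4)
    stop("brokers need at least 4 planted modules")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("'zero_inflation' must lie in [0, 1)")
  structure(list(groups = groups, samples_per_group = samples_per_group,
                 n_otu = n_otu, module_sizes = as.integer(module_sizes),
                 rho_w = rho_w, rho_b = rho_b, f_neg = f_neg,
                 n_brokers = n_brokers,
                 meanlog = meanlog, sdlog_between = sdlog_between,
                 sdlog_within = sdlog_within,
                 zero_inflation = zero_inflation,
                 depth = depth, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic OTU table with known ground truth
#'
#' Draws latent block-correlated normals per sample (see [synthetic_spec]),
#' maps them through the exponential link onto a lognormal baseline, and
#' converts to integer counts with a Poisson draw at the target depth
#' (lognormal-Poisson counts).  Module membership, latent sign flips,
#' broker identities and per-module hub designations are returned as ground
#' truth so downstream recovery can be scored without re-deriving it.
#'
#' Synthetic taxonomy cycles planted modules through common gut phyla
#' (Firmicutes, Bacteroidetes, Proteobacteria, Fusobacteria,
#' Actinobacteria); background OTUs are labelled Firmicutes.
#'
#' @param spec A [synthetic_spec].
#' @return List with \code{table} (an [otu_table] in counts units, with
#'   taxonomy and groups) and \code{truth} (list: \code{membership} named
#'   integer, 0 for background; \code{flipped} named logical;
#'   \code{brokers}, \code{hubs} character vectors; \code{spec}).
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_mod <- length(spec$module_sizes)
  n_in_mod <- sum(spec$module_sizes)
  n_bg <- spec$n_otu - n_in_mod - spec$n_brokers
  otu_ids <- sprintf("OTU%d", seq_len(spec$n_otu))

  membership <- c(rep(seq_len(n_mod), spec$module_sizes),
                  rep(0L, spec$n_brokers + n_bg))
  names(membership) <- otu_ids
  brokers <- if (spec$n_brokers > 0)
    otu_ids[n_in_mod + seq_len(spec$n_brokers)] else character(0)
  # broker b loads evenly on modules (b, b+1, b+2, b+3) mod n_mod
  broker_mods <- lapply(seq_len(spec$n_brokers), function(b)
    ((b - 1 + 0:3) %% n_mod) + 1)

  # hub designation: first member of each module loads purely on its factor
  mod_start <- cumsum(c(0, spec$module_sizes[-n_mod])) + 1
  hubs <- otu_ids[mod_start]

  # axis reflection: flip a fraction phi of non-hub members per module so the
  # negative within-module coupling fraction is ~ 2*phi*(1-phi) = f_neg
  phi <- (1 - sqrt(1 - 2 * spec$f_neg)) / 2
  flipped <- stats::setNames(rep(FALSE, spec$n_otu), otu_ids)
  for (m in seq_len(n_mod)) {
    members <- otu_ids[membership == m]
    q <- round(spec$module_sizes[m] * phi)
    candidates <- setdiff(members, hubs)
    if (q > 0) flipped[sample(candidates, min(q, length(candidates)))] <- TRUE
  }

  mu_i <- stats::rnorm(spec$n_otu, spec$meanlog, spec$sdlog_between)
  tau <- if (spec$rho_w > 0) spec$rho_b / spec$rho_w else 0
  n_samp <- spec$samples_per_group * length(spec$groups)
  sample_ids <- unlist(lapply(spec$groups, function(g)
    sprintf("%s_S%02d", g, seq_len(spec$samples_per_group))))
  groups <- stats::setNames(rep(spec$groups, each = spec$samples_per_group),
                            sample_ids)

  counts <- matrix(0L, spec$n_otu, n_samp,
                   dimnames = list(otu_ids, sample_ids))
  is_hub <- otu_ids %in% hubs
  for (j in seq_len(n_samp)) {
    cbg <- stats::rnorm(1)
    g <- sqrt(tau) * cbg + sqrt(1 - tau) * stats::rnorm(n_mod)
    z <- numeric(spec$n_otu)
    in_mod <- membership > 0
    eps <- stats::rnorm(spec$n_otu)
    z[in_mod] <- sqrt(spec$rho_w) * g[membership[in_mod]] +
      ifelse(is_hub[in_mod], 0, sqrt(1 - spec$rho_w) * eps[in_mod])
    # pure-factor hubs keep unit-order variance via the factor itself
    bg_idx <- which(membership == 0 & !(otu_ids %in% brokers))
    z[bg_idx] <- sqrt(spec$rho_b) * cbg + sqrt(1 - spec$rho_b) * eps[bg_idx]
    for (b in seq_along(brokers)) {
      mods <- broker_mods[[b]]
      z[match(brokers[b], otu_ids)] <- sum(g[mods]) / sqrt(4 + 12 * tau)
    }
    z <- ifelse(flipped, -z, z)
    lam <- exp(mu_i + spec$sdlog_within * z)
    if (spec$zero_inflation > 0)
      lam[stats::runif(spec$n_otu) < spec$zero_inflation] <- 0
    p <- lam / sum(lam)
    counts[, j] <- stats::rpois(spec$n_otu, spec$depth * p)
  }

  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Fusobacteria", "Actinobacteria")
  lineage <- stats::setNames(
    sprintf("Bacteria;%s",
            ifelse(membership > 0,
                   phyla[(membership - 1L) %% length(phyla) + 1L],
                   "Firmicutes")),
    otu_ids)

  table <- otu_table(counts, taxonomy = lineage, groups = groups,
                     units = "counts")
  truth <- list(membership = membership, flipped = flipped,
                brokers = brokers, hubs = hubs, spec = spec)
  list(table = table, truth = truth)
}

#' Generate tumour-marker values coupled to a network quantity
#'
#' Each marker is a linear function of a supplied per-sample (or per-group)
#' network quantity plus Gaussian noise:
#' marker = coupling * quantity + N(0, noise_sd).  Negative couplings plant
#' negative Spearman associations between the marker and the quantity; zero
#' couplings give pure-noise markers.
#'
#' @param quantity Named numeric vector.  Names are sample ids, or group
#'   labels if \code{groups} is supplied (each sample then inherits its
#'   group's value).
#' @param coupling Named numeric vector of coupling coefficients, one per
#'   marker (default the four CRC serum markers, all zero).
#' @param noise_sd Gaussian noise SD (same units as the marker).
#' @param groups Optional named character vector sample id -> group label.
#' @param seed Optional integer seed.
#' @return Data frame of marker values, row names = sample ids.
#' @export
generate_markers <- function(quantity,
                             coupling = c(CA242 = 0, CEA = 0,
                                          CA199 = 0, CA724 = 0),
                             noise_sd = 0, groups = NULL, seed = NULL) {
  if (is.null(names(quantity))) stop("'quantity' must be named")
  if (is.null(names(coupling))) stop("'coupling' must be named by marker")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(groups)) {
    if (!all(groups %in% names(quantity)))
      stop("some groups lack a quantity value")
    quantity <- stats::setNames(quantity[groups], names(groups))
  }
  out <- as.data.frame(lapply(coupling, function(cc)
    cc * quantity + stats::rnorm(length(quantity), 0, noise_sd)))
  rownames(out) <- names(quantity)
  out
}
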