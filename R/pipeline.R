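#' Reference topology panel for the intestinal microbiota networks
#'
#' The published panel of global topology indices for seven intestinal
#' microbiota co-occurrence networks: one healthy group (H) and six
#' chemotherapy stages (T0-T5), all built at the identical RMT-selected
#' similarity threshold 0.660, together with the random-network
#' (degree-preserving null) means and standard deviations over ensembles of
#' 100.  Used for arithmetic self-consistency checks (average degree =
#' 2E/N) and for the percentage-change statements comparing groups.
#'
#' @return Data frame, one row per group, with columns: group,
#'   original_otus, network_size, total_links, average_degree,
#'   average_path_distance, average_clustering_coefficient,
#'   average_harmonic_geodesic_distance, threshold, power_law_r2,
#'   modularity, and the random-network columns rand_path_mean, rand_path_sd,
#'   rand_clustering_mean, rand_clustering_sd, rand_harmonic_mean,
#'   rand_harmonic_sd, rand_modularity_mean, rand_modularity_sd.
#' @export
reference_indices <- function() {
  data.frame(
    group = c("H", "T0", "T1", "T2", "T3", "T4", "T5"),
    original_otus = c(655, 778, 727, 793, 814, 788, 758),
    network_size = c(105, 99, 102, 103, 80, 103, 103),
    total_links = c(110, 238, 228, 239, 173, 210, 231),
    average_degree = c(2.095, 4.808, 4.471, 4.641, 4.325, 4.078, 4.485),
    average_path_distance = c(5.942, 2.893, 2.982, 3.216, 3.403, 3.701, 3.210),
    average_clustering_coefficient =
      c(0.07, 0.191, 0.209, 0.175, 0.140, 0.119, 0.240),
    average_harmonic_geodesic_distance =
      c(4.165, 2.488, 2.539, 2.759, 2.717, 3.022, 2.668),
    threshold = rep(0.660, 7),
    power_law_r2 = c(0.786, 0.794, 0.724, 0.821, 0.808, 0.861, 0.870),
    modularity = c(0.773, 0.429, 0.450, 0.475, 0.405, 0.500, 0.498),
    rand_path_mean = c(5.584, 2.693, 2.705, 3.02, 2.883, 3.228, 3.022),
    rand_path_sd = c(0.467, 0.045, 0.047, 0.052, 0.068, 0.069, 0.064),
    rand_clustering_mean = c(0.014, 0.209, 0.200, 0.101, 0.139, 0.077, 0.102),
    rand_clustering_sd = c(0.010, 0.025, 0.024, 0.018, 0.022, 0.017, 0.018),
    rand_harmonic_mean = c(4.318, 2.401, 2.415, 2.635, 2.509, 2.803, 2.647),
    rand_harmonic_sd = c(0.254, 0.026, 0.026, 0.031, 0.042, 0.043, 0.039),
    rand_modularity_mean = c(0.731, 0.355, 0.381, 0.393, 0.380, 0.434, 0.396),
    rand_modularity_sd = c(0.015, 0.010, 0.010, 0.011, 0.011, 0.012, 0.011)
  )
}

#' Percentage change of a value relative to a reference
#'
#' Returns (value - reference) / reference * 100.  Published group
#' comparisons use two conventions, depending on the statement: a change of
#' X "compared with" Y is sometimes expressed relative to X's own group and
#' sometimes relative to the comparator, so the reference is an explicit
#' argument rather than a fixed side.
#'
#' @param value The value whose change is described.
#' @param reference The denominator of the percentage.
#' @return Signed percentage (positive = value exceeds reference).
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("reference value of 0")
  (value - reference) / reference * 100
}

#' Run the full network pipeline on a multi-group OTU table
#'
#' Per group: rarefaction (optional), prevalence filtering (> 50 percent of
#' the group's samples by default), relative-abundance conversion, absolute
#' Pearson similarity, threshold selection (RMT scan, or an imposed common
#' St), signed network construction, module detection, global indices, Z-P
#' node roles, and a degree-preserving null ensemble.  Across groups:
#' Student t comparisons of the null-assessed indices and, when markers are
#' given, the degree-by-marker Spearman association grid over per-group
#' means.
#'
#' @param x An [otu_table] in counts units with group assignments.
#' @param markers Optional data frame of tumour-marker values (row names =
#'   sample ids).
#' @param st Imposed similarity threshold; \code{NULL} (default) selects St
#'   per group by [scan_threshold].
#' @param rarefy_depth Rarefaction depth, or \code{NULL} to skip rarefaction.
#' @param min_fraction Prevalence fraction that must be strictly exceeded.
#' @param n_random Null-ensemble size per group (default 100).
#' @param min_module_size Minimum module size for composition reporting.
#' @param seed Master seed for rarefaction and null ensembles.
#' @return Object of class \code{"pmen_run"}: list with \code{groups} (per
#'   group: table, similarity, scan, st, network, partition, indices, zp,
#'   ensemble, composition), \code{summary} (group x index data frame),
#'   \code{comparisons} (pairwise t-tests) and \code{associations}.
#' @export
run_pipeline <- function(x, markers = NULL, st = NULL,
                         rarefy_depth = 39796, min_fraction = 0.5,
                         n_random = 100, min_module_size = 5, seed = 1) {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(x$groups)) stop("table carries no group assignment")
  group_levels <- unique(unname(x$groups))
  if (!is.null(rarefy_depth)) x <- rarefy(x, depth = rarefy_depth, seed = seed)
  res <- list()
  for (g in group_levels) {
    stage <- "prevalence_filter"
    out <- tryCatch({
      filt <- prevalence_filter(x, g, min_fraction = min_fraction)
      rel <- relative_abundance(filt)
      stage <- "pearson_similarity"
      smat <- pearson_similarity(rel)
      stage <- "threshold"
      scan <- NULL
      st_g <- st
      if (is.null(st_g)) {
        scan <- scan_threshold(smat)
        st_g <- scan$st
      }
      stage <- "build_network"
      net <- build_network(smat, st = st_g)
      stage <- "modules_and_indices"
      part <- detect_modules(net)
      ind <- global_indices(net, part)
      stage <- "node_roles"
      zp <- zp_table(net, part, taxonomy = rel$taxonomy)
      stage <- "null_ensemble"
      ens <- ensemble_indices(net, n = n_random, seed = seed)
      comp <- module_composition(net, part, taxonomy = rel$taxonomy,
                                 min_size = min_module_size)
      list(table = rel, similarity = smat, scan = scan, st = st_g,
           network = net, partition = part, indices = ind, zp = zp,
           ensemble = ens, composition = comp)
    }, error = function(e)
      stop("pipeline stage '", stage, "' failed for group '", g, "': ",
           conditionMessage(e), call. = FALSE))
    res[[g]] <- out
  }
  summary <- do.call(rbind, lapply(group_levels, function(g)
    cbind(data.frame(group = g, st = res[[g]]$st), res[[g]]$indices)))
  rownames(summary) <- NULL

  comparisons <- NULL
  if (length(group_levels) >= 2) {
    pairs <- utils::combn(group_levels, 2, simplify = FALSE)
    rows <- list()
    for (p in pairs) {
      for (idx in c("average_path_distance", "average_clustering_coefficient",
                    "average_harmonic_geodesic_distance", "modularity")) {
        cmp <- compare_networks(res[[p[1]]]$indices[[idx]],
                                res[[p[1]]]$ensemble,
                                res[[p[2]]]$indices[[idx]],
                                res[[p[2]]]$ensemble, index = idx)
        rows[[paste(p[1], p[2], idx)]] <-
          data.frame(group_a = p[1], group_b = p[2], index = idx,
                     t = cmp$t, df = cmp$df, p_value = cmp$p_value)
      }
    }
    comparisons <- do.call(rbind, rows)
    rownames(comparisons) <- NULL
  } else {
    message("single group: cross-group comparison stage skipped")
  }

  associations <- NULL
  if (!is.null(markers) && length(group_levels) >= 3) {
    deg <- do.call(rbind, lapply(group_levels, function(g) {
      net <- res[[g]]$network
      data.frame(all = mean(otu_degree(net, "all")),
                 negative = mean(otu_degree(net, "negative")),
                 positive = mean(otu_degree(net, "positive")))
    }))
    mk <- do.call(rbind, lapply(group_levels, function(g) {
      ids <- intersect(names(x$groups)[x$groups == g], rownames(markers))
      colMeans(markers[ids, , drop = FALSE], na.rm = TRUE)
    }))
    associations <- degree_marker_table(deg, as.data.frame(mk))
  }

  structure(list(groups = res, summary = summary,
                 comparisons = comparisons, associations = associations),
            class = "pmen_run")
}

#' @export
print.pmen_run <- function(x, ...) {
  cat("pmen_run across", length(x$groups), "group(s)\n\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Empirical-plus-random summary table for a pipeline run
#'
#' Reshapes a [run_pipeline] result into the standard reporting layout: an
#' empirical block (one column per group, one row per topology index) over
#' a random-network block giving ensemble mean and SD for the four
#' null-assessed indices.
#'
#' @param run A \code{"pmen_run"}.
#' @param digits Rounding for display values.
#' @return Data frame with columns block, index, then one column per group.
#' @export
summary_table <- function(run, digits = 3) {
  stopifnot(inherits(run, "pmen_run"))
  groups <- names(run$groups)
  emp_idx <- c("network_size", "total_links", "average_degree",
               "average_path_distance", "average_clustering_coefficient",
               "average_harmonic_geodesic_distance", "power_law_r2",
               "modularity", "n_modules", "negative_link_fraction")
  emp <- data.frame(block = "empirical", index = emp_idx)
  for (g in groups)
    emp[[g]] <- vapply(emp_idx, function(i)
      round(run$groups[[g]]$indices[[i]], digits), numeric(1))
  rnd_idx <- c("average_path_distance", "average_clustering_coefficient",
               "average_harmonic_geodesic_distance", "modularity")
  rnd <- data.frame(block = "random", index = rnd_idx)
  for (g in groups) {
    ens <- run$groups[[g]]$ensemble
    rnd[[g]] <- sprintf("%s +/- %s",
                        round(ens$mean[rnd_idx], digits),
                        round(ens$sd[rnd_idx], digits))
  }
  emp[groups] <- lapply(emp[groups], as.character)
  rbind(emp, rnd)
}
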