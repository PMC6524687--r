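#' Construct an OTU abundance table
#'
#' The central data container of the package: a matrix of non-negative
#' abundances with OTUs as rows and samples as columns, an optional taxonomy
#' (semicolon-ranked lineage strings, kingdom to genus), and an optional
#' sample-to-group assignment.  A units marker records whether the values are
#' raw sequence counts or relative abundances (proportions).
#'
#' @param values Numeric matrix, OTUs in rows and samples in columns, with
#'   row and column names.  All entries must be non-negative and finite.
#' @param taxonomy Optional named character vector mapping OTU id to a
#'   semicolon-separated lineage string (e.g. \code{"Bacteria;Firmicutes;..."}).
#' @param groups Optional named character vector mapping sample id to a group
#'   label (e.g. \code{"H"}, \code{"T0"} ... \code{"T5"}).
#' @param units Either \code{"counts"} or \code{"proportions"}.  When
#'   \code{"proportions"}, every sample column must sum to 1 within 1e-9.
#'
#' @return An object of class \code{"otu_table"}: a list with elements
#'   \code{values}, \code{taxonomy}, \code{groups} and \code{units}.
#' @export
otu_table <- function(values, taxonomy = NULL, groups = NULL,
                      units = c("counts", "proportions")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (OTUs x samples)")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must carry OTU row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundances must be finite and non-negative")
  if (units == "proportions") {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9))
      stop("proportion columns must sum to 1 (tolerance 1e-9)")
  }
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      stop("'taxonomy' must be named by OTU id")
    taxonomy <- taxonomy[names(taxonomy) %in% rownames(values)]
  }
  if (!is.null(groups)) {
    if (is.null(names(groups)))
      stop("'groups' must be named by sample id")
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("samples without a group assignment: ",
           paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  }
  structure(
    list(values = values, taxonomy = taxonomy, groups = groups, units = units),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$units))
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s (%d)", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  if (!is.null(x$taxonomy))
    cat(sprintf("taxonomy available for %d OTUs\n", length(x$taxonomy)))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$values)

#' Read an OTU table from a tab-separated file
#'
#' Expects OTUs in rows and samples in columns: the first column holds OTU
#' ids, the header row holds sample ids, and an optional trailing
#' \code{taxonomy} column holds semicolon-separated lineages.
#'
#' @param path Path to a TSV file.
#' @param groups Optional named character vector (sample id to group label)
#'   attached to the result.
#' @param units Units of the stored values, \code{"counts"} by default.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, groups = NULL, units = "counts") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "")
  if (ncol(raw) < 2) stop("OTU table needs at least one sample column")
  otu_ids <- raw[[1]]
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU id in ", path, ": ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  body <- raw[, -1, drop = FALSE]
  taxonomy <- NULL
  if (tolower(names(body)[ncol(body)]) == "taxonomy") {
    taxonomy <- body[[ncol(body)]]
    names(taxonomy) <- otu_ids
    taxonomy <- taxonomy[nzchar(taxonomy)]
    body <- body[, -ncol(body), drop = FALSE]
  }
  values <- matrix(NA_real_, nrow(body), ncol(body),
                   dimnames = list(otu_ids, names(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric abundance at row '%s', sample '%s'",
                   otu_ids[bad[1]], names(body)[j]))
    values[, j] <- v
  }
  if (any(values < 0))
    stop("negative abundance in ", path)
  otu_table(values, taxonomy = taxonomy, groups = groups, units = units)
}

#' Write an OTU table in the TSV dialect read by [read_otu_table]
#'
#' @param x An [otu_table].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- data.frame(OTU_ID = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy))
    df$taxonomy <- unname(x$taxonomy[rownames(x$values)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (group design and tumour markers)
#'
#' Reads a TSV with columns \code{sample_id}, \code{group}, and any marker
#' columns (typically CA242, CEA, CA199, CA724).  Missing marker values are
#' allowed and read as NA.
#'
#' @param path Path to a TSV file.
#' @return A list with \code{groups} (named character vector) and
#'   \code{markers} (data frame, one row per sample, row names = sample ids).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  groups <- stats::setNames(as.character(df$group), df$sample_id)
  markers <- df[, setdiff(names(df), need), drop = FALSE]
  rownames(markers) <- df$sample_id
  list(groups = groups, markers = markers)
}

#' Rarefy (randomly subsample) each sample to a common depth
#'
#' Draws \code{depth} sequences per sample without replacement, so retained
#' counts are hypergeometric.  Samples whose total is below \code{depth} are
#' dropped with a warning rather than resampled with replacement.
#'
#' @param x An [otu_table] in counts units.
#' @param depth Target number of sequences per sample (default 39796, a
#'   typical post-QC depth for fecal 16S libraries of this design).
#' @param seed Optional integer seed; fixing it makes the draw reproducible.
#' @return A rarefied [otu_table]; every retained column sums to \code{depth}.
#' @export
rarefy <- function(x, depth = 39796, seed = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (x$units != "counts") stop("rarefy requires counts, not proportions")
  if (length(depth) != 1 || depth <= 0) stop("'depth' must be a positive integer")
  depth <- as.integer(round(depth))
  if (!is.null(seed)) set.seed(seed)
  cs <- colSums(x$values)
  shallow <- cs < depth
  if (all(shallow)) stop("no sample reaches the rarefaction depth")
  if (any(shallow))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(shallow), depth,
                    paste(colnames(x$values)[shallow], collapse = ", ")))
  keep <- which(!shallow)
  out <- matrix(0, nrow(x$values), length(keep),
                dimnames = list(rownames(x$values),
                                colnames(x$values)[keep]))
  n_otu <- nrow(x$values)
  for (j in seq_along(keep)) {
    counts <- as.integer(round(x$values[, keep[j]]))
    if (sum(counts) == depth) {       # exhaustive draw: nothing to subsample
      out[, j] <- counts
    } else {
      pool <- rep.int(seq_len(n_otu), counts)
      drawn <- pool[sample.int(length(pool), depth)]
      out[, j] <- tabulate(drawn, nbins = n_otu)
    }
  }
  otu_table(out, taxonomy = x$taxonomy,
            groups = if (is.null(x$groups)) NULL else x$groups[colnames(out)],
            units = "counts")
}

#' Prevalence filter within one group
#'
#' Restricts the table to the samples of one group and keeps an OTU only if
#' it is detected (abundance > 0) in strictly more than \code{min_fraction}
#' of that group's samples.  With the default 0.5 this is the usual
#' "present in more than 50\% of replicates" screen used before network
#' construction; an OTU present in exactly half of the samples is removed.
#'
#' @param x An [otu_table] with a group assignment.
#' @param group Group label to select.
#' @param min_fraction Detection fraction that must be strictly exceeded.
#' @return An [otu_table] restricted to the group's samples and the
#'   surviving OTUs.
#' @export
prevalence_filter <- function(x, group, min_fraction = 0.5) {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(x$groups)) stop("table carries no group assignment")
  if (!group %in% x$groups)
    stop("unknown group label: ", group)
  samples <- names(x$groups)[x$groups == group]
  if (length(samples) < 2) stop("group '", group, "' has fewer than 2 samples")
  sub <- x$values[, samples, drop = FALSE]
  detected <- rowSums(sub > 0)
  keep <- detected > min_fraction * length(samples)   # strict inequality
  otu_table(sub[keep, , drop = FALSE],
            taxonomy = x$taxonomy,
            groups = x$groups[samples],
            units = x$units)
}

#' Convert counts to relative abundances
#'
#' Divides every sample column by its total so columns sum to one.  Applying
#' it to a table already in proportions is an error (the conversion is a
#' one-way unit change, not an idempotent rescale).
#'
#' @param x An [otu_table] in counts units with no all-zero sample.
#' @return An [otu_table] in proportions units.
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  if (x$units != "counts")
    stop("relative_abundance expects counts input; table is already proportions")
  cs <- colSums(x$values)
  if (any(cs == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(x$values)[cs == 0], collapse = ", "))
  otu_table(sweep(x$values, 2, cs, "/"),
            taxonomy = x$taxonomy, groups = x$groups, units = "proportions")
}

#' Phylum of each OTU from its lineage string
#'
#' Lineages are semicolon-ranked, kingdom first, so the phylum is the second
#' field.  OTUs without taxonomy (or with fewer than two ranks) are reported
#' as "unclassified".
#'
#' @param taxonomy Named character vector of lineage strings, or NULL.
#' @param otu_ids OTU ids to look up.
#' @return Named character vector of phylum names.
#' @export
otu_phylum <- function(taxonomy, otu_ids) {
  out <- rep("unclassified", length(otu_ids))
  names(out) <- otu_ids
  if (is.null(taxonomy)) return(out)
  hit <- intersect(otu_ids, names(taxonomy))
  ranks <- strsplit(taxonomy[hit], ";", fixed = TRUE)
  phy <- vapply(ranks, function(r) {
    r <- trimws(r)
    if (length(r) >= 2 && nzchar(r[2])) r[2] else "unclassified"
  }, character(1))
  out[hit] <- phy
  out
}
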