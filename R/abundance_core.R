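# Relative / absolute abundance and the prevalence-abundance core framework.

#' Convert counts to relative abundance
#'
#' @param table a [count_table].
#' @return An `abundance_table` with `mode = "relative_fraction"`; every
#'   sample row sums to 1.
#' @export
to_relative <- function(table) {
  counts <- values_of(table)
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("zero-sum sample(s): ", paste(rownames(counts)[rs == 0], collapse = ", "))
  abundance_table(counts / rs, mode = "relative_fraction")
}

#' Construct an abundance table
#'
#' @param values numeric matrix, samples x taxa, with dimnames.
#' @param mode `"relative_fraction"` (rows sum to 1) or `"absolute_copies"`
#'   (16S copies per gut).
#' @return An `abundance_table`.
#' @export
abundance_table <- function(values, mode = c("relative_fraction",
                                             "absolute_copies")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (any(values < 0)) stop("negative abundance value")
  if (mode == "relative_fraction") {
    rs <- rowSums(values)
    bad <- abs(rs - 1) > 1e-9 & rs > 0
    if (any(bad))
      stop("relative abundance rows must sum to 1: ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  structure(list(values = values, mode = mode), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table (%s): %d samples x %d taxa\n",
              x$mode, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Scale relative abundances to absolute loads
#'
#' Multiplies each sample's relative abundances by its total bacterial load
#' from the qPCR panel (target `total_bacteria`), yielding 16S copies per gut.
#'
#' @param rel an `abundance_table` in relative mode.
#' @param panel a `qpcr_panel` with a `total_bacteria` row for every sample.
#' @return An `abundance_table` with `mode = "absolute_copies"`.
#' @export
to_absolute <- function(rel, panel) {
  if (!inherits(rel, "abundance_table") || rel$mode != "relative_fraction")
    stop("to_absolute() expects a relative abundance_table")
  loads <- qpcr_total_loads(panel, rownames(rel$values))
  if (any(loads == 0))
    warning("zero total bacterial load for sample(s): ",
            paste(names(loads)[loads == 0], collapse = ", "))
  abundance_table(rel$values * loads, mode = "absolute_copies")
}

#' Per-taxon prevalence
#'
#' Fraction of samples in which a taxon exceeds the detection threshold.
#'
#' @param table a [count_table] or `abundance_table`.
#' @param detection_min detection threshold; a taxon is "present" in a sample
#'   when its value is strictly greater. Default 0.
#' @return named numeric vector of exact fractions in `[0, 1]`.
#' @export
prevalence <- function(table, detection_min = 0) {
  v <- values_of(table)
  colMeans(v > detection_min)
}

#' Core microbiota criteria
#'
#' @param prevalence_min minimum prevalence fraction (default 0.80: present in
#'   at least 80\% of samples).
#' @param mean_rel_abundance_min minimum mean relative abundance across all
#'   samples, zeros included (default 1e-4, i.e. 0.01\%).
#' @param rank taxonomic rank at which to aggregate before testing
#'   (`"otu"` for no aggregation).
#' @param detection_min detection threshold for prevalence.
#' @return A `core_criteria` list.
#' @export
core_criteria <- function(prevalence_min = 0.80,
                          mean_rel_abundance_min = 1e-4,
                          rank = "otu", detection_min = 0) {
  stopifnot(prevalence_min >= 0, prevalence_min <= 1,
            mean_rel_abundance_min >= 0, mean_rel_abundance_min <= 1)
  if (!rank %in% c("otu", TAXONOMIC_RANKS))
    stop("unknown rank '", rank, "'; use \"otu\" or one of: ",
         paste(TAXONOMIC_RANKS, collapse = ", "))
  structure(list(prevalence_min = prevalence_min,
                 mean_rel_abundance_min = mean_rel_abundance_min,
                 rank = rank, detection_min = detection_min),
            class = "core_criteria")
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Raw counts are summed within the named rank before any conversion to
#' relative abundance (preserving compositional weighting). OTUs unassigned at
#' that rank are grouped by their deepest assigned name, labelled
#' `"unclassified_<name>"`.
#'
#' @param table a [count_table].
#' @param taxonomy a `taxonomy_table` covering the table's OTUs.
#' @param rank one of the canonical ranks.
#' @return A [count_table] of aggregated taxa.
#' @export
aggregate_to_rank <- function(table, taxonomy, rank) {
  if (!rank %in% TAXONOMIC_RANKS)
    stop("unknown rank '", rank, "'")
  counts <- table$counts
  idx <- match(colnames(counts), taxonomy$otu_id)
  if (anyNA(idx))
    stop("taxonomy missing for OTU(s): ",
         paste(colnames(counts)[is.na(idx)], collapse = ", "))
  lab <- taxonomy[[rank]][idx]
  deepest <- vapply(idx, function(i) {
    assigned <- unlist(taxonomy[i, TAXONOMIC_RANKS]) != "unassigned"
    w <- which(assigned)
    if (length(w)) unlist(taxonomy[i, TAXONOMIC_RANKS])[max(w)] else "unknown"
  }, "")
  lab <- ifelse(lab == "unassigned", paste0("unclassified_", deepest), lab)
  groups <- unique(lab)
  agg <- vapply(groups, function(g)
    rowSums(counts[, lab == g, drop = FALSE]), numeric(nrow(counts)))
  count_table(matrix(agg, nrow = nrow(counts),
                     dimnames = list(rownames(counts), groups)))
}

#' Detect the core microbiota
#'
#' Applies the joint prevalence / mean-relative-abundance framework: a taxon
#' is core iff `prevalence >= prevalence_min` and
#' `mean_rel_abundance >= mean_rel_abundance_min`. Comparisons use exact
#' fractions (with 17 samples, prevalence >= 0.80 means presence in at least
#' 14 = ceiling(0.8 * 17) samples). Mean relative abundance is the arithmetic
#' mean over all samples, zeros included.
#'
#' @param table a [count_table].
#' @param taxonomy a `taxonomy_table`; required when `criteria$rank != "otu"`.
#' @param criteria a [core_criteria].
#' @return A `core_result`: list with `summary` (data frame of per-taxon
#'   `taxon`, `prevalence`, `mean_rel_abundance`, `is_core` — also the
#'   prevalence-abundance scatter coordinates) and `core_ids`.
#' @export
detect_core <- function(table, taxonomy = NULL, criteria = core_criteria()) {
  if (criteria$rank != "otu") {
    if (is.null(taxonomy))
      stop("rank-level core detection needs a taxonomy table")
    table <- aggregate_to_rank(table, taxonomy, criteria$rank)
  }
  prev <- prevalence(table, criteria$detection_min)
  mra <- colMeans(to_relative(table)$values)
  is_core <- prev >= criteria$prevalence_min &
    mra >= criteria$mean_rel_abundance_min
  summary <- data.frame(taxon = names(prev), prevalence = unname(prev),
                        mean_rel_abundance = unname(mra),
                        is_core = unname(is_core), stringsAsFactors = FALSE)
  structure(list(summary = summary,
                 core_ids = summary$taxon[summary$is_core],
                 criteria = criteria),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf("core_result: %d of %d taxa are core (prevalence >= %g, mean RA >= %g)\n",
              length(x$core_ids), nrow(x$summary),
              x$criteria$prevalence_min, x$criteria$mean_rel_abundance_min))
  invisible(x)
}
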