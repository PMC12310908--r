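# Abundance-weighted functional capacity scores.
#
# Each genus carries a capacity vector: the number of annotated metabolic
# pathways (or enzymes, EC) per category in its type-strain genome. A sample's
# raw score for a category is the relative-abundance-weighted sum of
# capacities over the genera present; "predicted score values" re-express the
# raw scores as percentages within each sample.

TABLE1_CHECKSUM <- "43d4ec7efe41133f9c6277bcfda40c18"

#' The twelve packaged pathway classes, in canonical order
#' @return character vector of class labels.
#' @export
pathway_classes <- function() {
  c("amino_acid_synthesis", "fatty_acid_biosynthesis", "monosaccharides",
    "nitrogen_metabolism", "protein_degradation", "resistance_to_antibiotics",
    "toxic_compounds_resistance", "vitamins", "alkaloids_degradation",
    "hormones", "metabolism_of_aromatic_compounds",
    "polysaccharides_degradation")
}

#' Construct a capacity matrix
#'
#' @param m matrix of non-negative integer pathway/enzyme counts, taxa in
#'   rows, categories in columns, with dimnames.
#' @return A `capacity_matrix`.
#' @export
capacity_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("capacity matrix needs taxon row names and category column names")
  if (any(m < 0) || any(m != round(m)))
    stop("capacities must be non-negative integers")
  structure(m, class = c("capacity_matrix", "matrix", "array"))
}

#' Load the packaged genus x pathway-class capacity table
#'
#' Ten gut genera of Poecilus ground beetles (Apilactobacillus, Bacillus,
#' Carnobacterium, Enterobacter, Enterococcus, Gilliamella, Lactobacillus,
#' Lactococcus, Staphylococcus, Weissella) by the twelve
#' [pathway_classes()], as annotated pathway counts of type-strain genomes.
#' The file's checksum is verified on load.
#'
#' @return A `capacity_matrix` (10 x 12).
#' @export
load_capacity_fixture <- function() {
  path <- system.file("extdata", "table1_pathway_capacity.tsv",
                      package = "beetlegut", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != TABLE1_CHECKSUM)
    stop("packaged capacity fixture failed its checksum")
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  if (!identical(colnames(m), pathway_classes()))
    stop("capacity fixture columns do not match the canonical class set")
  capacity_matrix(m)
}

#' Abundance-weighted functional scores
#'
#' `raw_score(s, cat) = sum_g RA(s, g) * C(g, cat)` over the genera of the
#' capacity matrix; `predicted_score_value = 100 * raw / total(s)` (the
#' per-sample percent normalization), `total_score(s) = sum_cat raw`.
#' Taxa in the abundance table with no capacity row are reported in the
#' `skipped` attribute, never silently dropped.
#'
#' @param abund an `abundance_table` (relative fractions; conventionally the
#'   core taxa renormalized to sum to 1, see [core_genus_abundance]).
#' @param cap a `capacity_matrix` with genus rows.
#' @return A `score_table`: list of matrices `raw` (samples x categories),
#'   `predicted_score_value`, vector `total_score`, character `skipped`,
#'   logical `flagged` (samples whose total score is 0, where the percent
#'   normalization is undefined).
#' @export
functional_scores <- function(abund, cap) {
  if (!inherits(abund, "abundance_table") || abund$mode != "relative_fraction")
    stop("functional_scores() expects a relative abundance_table")
  ra <- abund$values
  matched <- intersect(colnames(ra), rownames(cap))
  skipped <- setdiff(colnames(ra), rownames(cap))
  if (!length(matched))
    stop("no abundance taxon matches a capacity-matrix taxon")
  raw <- ra[, matched, drop = FALSE] %*% cap[matched, , drop = FALSE]
  total <- rowSums(raw)
  flagged <- total == 0
  psv <- raw
  psv[!flagged, ] <- 100 * raw[!flagged, , drop = FALSE] / total[!flagged]
  psv[flagged, ] <- NA_real_
  structure(list(raw = raw, predicted_score_value = psv,
                 total_score = total, skipped = skipped, flagged = flagged),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d samples x %d categories; total scores %s..%s\n",
              nrow(x$raw), ncol(x$raw),
              format(min(x$total_score), digits = 6),
              format(max(x$total_score), digits = 6)))
  if (length(x$skipped))
    cat(" skipped (no capacity row):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.score_table <- function(x, ...) {
  df <- data.frame(sample_id = rep(rownames(x$raw), ncol(x$raw)),
                   category = rep(colnames(x$raw), each = nrow(x$raw)),
                   raw_score = as.vector(x$raw),
                   predicted_score_value = as.vector(x$predicted_score_value),
                   stringsAsFactors = FALSE)
  df[order(df$sample_id, df$category), , drop = FALSE]
}

#' Genus-level core relative abundance for the scorer
#'
#' Restricts a count table to the core taxa, aggregates them to genus via the
#' taxonomy, and renormalizes so each sample's core composition sums to 1
#' (set `renormalize = FALSE` to keep whole-community fractions).
#'
#' @param table a [count_table] (typically MI-filtered).
#' @param taxonomy a `taxonomy_table`.
#' @param core a `core_result` from [detect_core] at OTU rank.
#' @param renormalize renormalize over core taxa (default TRUE).
#' @return An `abundance_table` over genera.
#' @export
core_genus_abundance <- function(table, taxonomy, core, renormalize = TRUE) {
  keep <- intersect(otu_ids(table), core$core_ids)
  if (!length(keep)) stop("no core taxa present in the table")
  sub <- count_table(table$counts[, keep, drop = FALSE])
  genus <- aggregate_to_rank(sub, taxonomy, "genus")
  if (renormalize) return(to_relative(genus))
  frac <- genus$counts / rowSums(table$counts)
  structure(list(values = frac, mode = "relative_fraction"),
            class = "abundance_table")
}

valid_ec <- function(ec) grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)

#' Per-enzyme (EC) scores with top-k ranking
#'
#' The same abundance-weighted rule applied to a genus x EC capacity table,
#' plus a per-sample top-k ranking (ties broken by EC label, ascending).
#'
#' @param abund relative `abundance_table` over genera.
#' @param ec_cap `capacity_matrix` with EC-number columns (`x.x.x.x`).
#' @param k ranking depth (default 10); when fewer ECs exist, all are ranked.
#' @return list with `scores` (a `score_table`) and `top` (data frame
#'   `sample_id`, `rank`, `ec`, `raw_score`, `predicted_score_value`).
#' @export
ec_scores <- function(abund, ec_cap, k = 10) {
  bad <- colnames(ec_cap)[!valid_ec(colnames(ec_cap))]
  if (length(bad))
    stop("malformed EC label(s): ", paste(bad, collapse = ", "))
  st <- functional_scores(abund, ec_cap)
  top <- do.call(rbind, lapply(rownames(st$raw), function(s) {
    v <- st$raw[s, ]
    ord <- order(-v, names(v))
    kk <- min(k, length(v))
    data.frame(sample_id = s, rank = seq_len(kk), ec = names(v)[ord][seq_len(kk)],
               raw_score = unname(v[ord])[seq_len(kk)],
               predicted_score_value =
                 unname(st$predicted_score_value[s, ord])[seq_len(kk)],
               stringsAsFactors = FALSE)
  }))
  rownames(top) <- NULL
  list(scores = st, top = top)
}

#' Read an offline EC-to-pathway map
#'
#' Two-column TSV snapshot (`ec`, `pathway_id`); one row per (EC, pathway)
#' link. No network access is ever made.
#'
#' @param path TSV file path.
#' @return data frame `ec`, `pathway_id`.
#' @export
read_ec_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ec", "pathway_id") %in% names(df)))
    stop("EC map needs columns 'ec' and 'pathway_id'")
  bad <- unique(df$ec[!valid_ec(df$ec)])
  if (length(bad))
    stop("malformed EC label(s) in map: ", paste(bad, collapse = ", "))
  df[, c("ec", "pathway_id")]
}

#' Aggregate EC scores to pathways
#'
#' Each EC contributes its full score to every pathway it maps to (fan-out);
#' ECs absent from the map accumulate in an `"unmapped"` bucket so that mass
#' is conserved: `sum(pathways) + unmapped = sum_ec score * fanout`.
#'
#' @param scores a `score_table` over ECs (from [ec_scores]).
#' @param map data frame `ec`, `pathway_id` (see [read_ec_map]).
#' @return A `score_table` over pathways (raw scores; percent normalization
#'   recomputed over pathways + unmapped).
#' @export
aggregate_ec_to_pathways <- function(scores, map) {
  raw <- scores$raw
  pws <- sort(unique(map$pathway_id))
  out <- matrix(0, nrow(raw), length(pws) + 1,
                dimnames = list(rownames(raw), c(pws, "unmapped")))
  for (ec in colnames(raw)) {
    hit <- map$pathway_id[map$ec == ec]
    if (length(hit)) {
      for (p in hit) out[, p] <- out[, p] + raw[, ec]
    } else {
      out[, "unmapped"] <- out[, "unmapped"] + raw[, ec]
    }
  }
  total <- rowSums(out)
  flagged <- total == 0
  psv <- out
  psv[!flagged, ] <- 100 * out[!flagged, , drop = FALSE] / total[!flagged]
  psv[flagged, ] <- NA_real_
  structure(list(raw = out, predicted_score_value = psv,
                 total_score = total, skipped = character(0),
                 flagged = flagged),
            class = "score_table")
}
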