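# ---- domain types -----------------------------------------------------------

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species")

RANK_PREFIXES <- c(domain = "k__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__",
                   species = "s__")

#' Construct a validated OTU count table
#'
#' The central object of the pipeline: a samples x OTUs matrix of non-negative
#' integer read counts with unique sample and OTU identifiers.
#'
#' @param counts numeric matrix, samples in rows, OTUs in columns. Row and
#'   column names are used as sample and OTU identifiers; alternatively pass
#'   `sample_ids`/`otu_ids`.
#' @param sample_ids,otu_ids optional character vectors overriding dimnames.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, sample_ids = rownames(counts),
                        otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("count table is empty")
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("count table needs sample and OTU identifiers")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU identifiers: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 sample_ids[bad[1]], otu_ids[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-9)) {
    bad <- which(abs(counts - round(counts)) > 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 sample_ids[bad[1]], otu_ids[bad[2]]))
  }
  counts <- round(counts)
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max in sums
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("zero-sum sample(s): ", paste(sample_ids[rs == 0], collapse = ", "))
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(list(counts = counts), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Sample identifiers of a pipeline object
#' @param x a `count_table` or `abundance_table`.
#' @return character vector of sample identifiers.
#' @export
sample_ids <- function(x) rownames(values_of(x))

#' OTU / taxon identifiers of a pipeline object
#' @param x a `count_table` or `abundance_table`.
#' @return character vector of taxon identifiers.
#' @export
otu_ids <- function(x) colnames(values_of(x))

values_of <- function(x) {
  if (inherits(x, "count_table")) return(x$counts)
  if (inherits(x, "abundance_table")) return(x$values)
  stop("expected a count_table or abundance_table")
}

# ---- count table IO ---------------------------------------------------------

#' Read an OTU count table
#'
#' Reads either the classic tab-separated QIIME-style table (sentinel header
#' cell `#OTU ID`, OTUs in rows) or a BIOM format v1.0 (JSON) file. Tables are
#' normalized to the samples x OTUs orientation. Orientation of a classic
#' table without the sentinel is controlled by `orientation`.
#'
#' @param path file path.
#' @param format `"auto"` (default; BIOM when the file parses as JSON with a
#'   `"matrix_type"` key, classic otherwise), `"classic_tsv"` or `"biom_json"`.
#' @param orientation for classic tables without the `#OTU ID` sentinel:
#'   `"otus_in_rows"` or `"samples_in_rows"`.
#' @return A [count_table].
#' @export
read_count_table <- function(path,
                             format = c("auto", "classic_tsv", "biom_json"),
                             orientation = c("otus_in_rows", "samples_in_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("matrix_type", head1) ||
                  grepl("^\\s*\\{", head1)) "biom_json" else "classic_tsv"
  }
  if (format == "biom_json") {
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))    # observations x samples
    return(count_table(t(m)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr_idx <- which(grepl("^#OTU ID\t", lines) | lines == "#OTU ID")[1]
  if (!is.na(hdr_idx)) {
    orientation <- "otus_in_rows"
    lines <- lines[hdr_idx:length(lines)]
    lines[1] <- sub("^#", "", lines[1])
  } else {
    lines <- lines[!grepl("^#", lines)]
  }
  if (length(lines) < 2L) stop("empty table: ", path)
  df <- utils::read.delim(text = lines, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table has no count columns: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(df[, -1, drop = FALSE])[!vapply(df[-1], is.numeric, TRUE)][1]
    stop("non-numeric counts in column '", bad, "' of ", path)
  }
  rownames(m) <- ids
  if (orientation == "otus_in_rows") m <- t(m)
  count_table(m)
}

#' Write a tabular pipeline object
#'
#' Deterministic serialization of the pipeline's tabular types: fixed column
#' and row order, floating point values at 6 significant digits.
#'
#' @param obj object to write.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @param ... passed to methods.
#' @return `invisible(path)`.
#' @export
write_table <- function(obj, path, format = c("tsv", "json"), ...) {
  UseMethod("write_table")
}

fmt_num <- function(x) {
  if (is.numeric(x) && !all(x == round(x)))
    return(formatC(signif(x, 6), format = "fg", flag = "#"))
  x
}

write_df <- function(df, path, format) {
  if (format == "json") {
    jsonlite::write_json(df, path, digits = 6, auto_unbox = FALSE)
  } else {
    out <- df
    for (j in seq_along(out)) out[[j]] <- fmt_num(out[[j]])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
write_table.data.frame <- function(obj, path, format = c("tsv", "json"), ...) {
  write_df(obj, path, match.arg(format))
}

#' @rdname write_table
#' @export
write_table.count_table <- function(obj, path, format = c("tsv", "json"), ...) {
  format <- match.arg(format)
  m <- t(obj$counts)                              # classic dialect: OTUs x samples
  if (format == "json") {
    jsonlite::write_json(list(otu_ids = rownames(m),
                              sample_ids = colnames(m),
                              counts = unname(m)),
                         path, digits = NA)
    return(invisible(path))
  }
  df <- data.frame(`#OTU ID` = rownames(m), m, check.names = FALSE)
  names(df)[-1] <- colnames(m)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
write_table.abundance_table <- function(obj, path, format = c("tsv", "json"),
                                        ...) {
  df <- data.frame(sample_id = sample_ids(obj),
                   as.data.frame(obj$values), check.names = FALSE)
  write_df(df, path, match.arg(format))
}

#' @rdname write_table
#' @export
write_table.score_table <- function(obj, path, format = c("tsv", "json"), ...) {
  write_df(as.data.frame(obj), path, match.arg(format))
}

#' @rdname write_table
#' @export
write_table.taxonomy_table <- function(obj, path, format = c("tsv", "json"),
                                       ...) {
  format <- match.arg(format)
  lineage <- vapply(seq_len(nrow(obj)), function(i) {
    r <- unlist(obj[i, TAXONOMIC_RANKS])
    keep <- r != "unassigned"
    paste0(RANK_PREFIXES[keep], r[keep], collapse = ";")
  }, "")
  df <- data.frame(otu_id = obj$otu_id, lineage = lineage,
                   stringsAsFactors = FALSE)
  if (format == "json") {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
write_table.qpcr_panel <- function(obj, path, format = c("tsv", "json"), ...) {
  format <- match.arg(format)
  df <- as.data.frame(unclass(obj), stringsAsFactors = FALSE)
  names(df) <- c("sample", "target", "quantity", "unit")  # long-format dialect
  if (format == "tsv") {
    utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, digits = NA)
  }
  invisible(path)
}

# ---- taxonomy ---------------------------------------------------------------

parse_lineage <- function(s) {
  out <- stats::setNames(rep("unassigned", length(TAXONOMIC_RANKS)),
                         TAXONOMIC_RANKS)
  if (is.na(s) || !nzchar(trimws(s))) return(out)
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  k <- 0L
  for (p in parts) {
    pref <- substr(p, 1, 3)
    hit <- match(pref, RANK_PREFIXES)
    if (!is.na(hit)) {
      name <- substring(p, 4)
      k <- hit
    } else {
      name <- p
      k <- k + 1L
    }
    if (k > length(TAXONOMIC_RANKS)) break
    if (nzchar(name)) out[k] <- name
  }
  out
}

#' Read an OTU taxonomy table
#'
#' Parses a two-column (OTU id, semicolon-delimited lineage) TSV into ranked
#' lineages over domain..species. Greengenes-style `k__`/`p__`/... prefixes are
#' recognized; bare names are assigned to successive ranks. Ranks deeper than
#' the assignment are explicit `"unassigned"`.
#'
#' @param path file path.
#' @param table optional [count_table]; OTUs present in the taxonomy but
#'   absent from the table trigger a warning (and are retained).
#' @return A `taxonomy_table`: data frame with `otu_id`, one column per rank,
#'   and `resolution_rank` (deepest assigned rank, `"none"` if empty).
#' @export
read_taxonomy <- function(path, table = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("otu_id", "lineage")[1:2],
                          comment.char = "#", quote = "")
  if (ncol(df) < 2L) stop("taxonomy file must have two columns: ", path)
  taxonomy_table(df[[1]], df[[2]], table = table)
}

#' Construct a taxonomy table from lineage strings
#'
#' @param otu_id character vector of OTU identifiers (unique).
#' @param lineage character vector of semicolon-delimited lineages.
#' @param table optional [count_table] for cross-checking (see
#'   [read_taxonomy]).
#' @return A `taxonomy_table` data frame.
#' @export
taxonomy_table <- function(otu_id, lineage, table = NULL) {
  otu_id <- as.character(otu_id)
  if (anyDuplicated(otu_id))
    stop("OTU listed twice in taxonomy: ",
         paste(unique(otu_id[duplicated(otu_id)]), collapse = ", "))
  ranks <- t(vapply(as.character(lineage), parse_lineage,
                    character(length(TAXONOMIC_RANKS)), USE.NAMES = FALSE))
  colnames(ranks) <- TAXONOMIC_RANKS
  assigned <- ranks != "unassigned"
  res <- apply(assigned, 1, function(a) {
    w <- which(a)
    if (length(w)) TAXONOMIC_RANKS[max(w)] else "none"
  })
  out <- data.frame(otu_id = otu_id, ranks, resolution_rank = res,
                    stringsAsFactors = FALSE)
  if (!is.null(table)) {
    extra <- setdiff(out$otu_id, otu_ids(table))
    if (length(extra))
      warning("taxonomy lists OTUs absent from the count table: ",
              paste(extra, collapse = ", "))
  }
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

# ---- qPCR panel -------------------------------------------------------------

KNOWN_QPCR_UNITS <- c("16S copies/gut", "16S rRNA copies/gut", "copies/gut",
                      "luxS copies/gut", "spores/gut")

#' Read a long-format qPCR panel
#'
#' Long CSV with columns `sample`, `target`, `quantity`, `unit`. A missing
#' (sample, target) row means "not detected", which is distinct from a
#' measured quantity of zero.
#'
#' @param path CSV file path.
#' @return A `qpcr_panel` data frame with columns `sample_id`, `target`,
#'   `quantity`, `unit`.
#' @export
read_qpcr_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "quantity", "unit")
  if (!all(need %in% names(df)))
    stop("qPCR panel needs columns: ", paste(need, collapse = ", "))
  qpcr_panel(df$sample, df$target, df$quantity, df$unit)
}

#' Construct a qPCR panel
#'
#' @param sample_id,target character vectors.
#' @param quantity non-negative numeric vector (per-gut units).
#' @param unit character vector of unit labels.
#' @return A `qpcr_panel` data frame.
#' @export
qpcr_panel <- function(sample_id, target, quantity, unit) {
  df <- data.frame(sample_id = as.character(sample_id),
                   target = as.character(target),
                   quantity = as.numeric(quantity),
                   unit = as.character(unit),
                   stringsAsFactors = FALSE)
  if (anyNA(df$quantity)) stop("non-numeric qPCR quantity")
  if (any(df$quantity < 0)) {
    bad <- df[df$quantity < 0, ][1, ]
    stop(sprintf("negative qPCR quantity for (%s, %s)",
                 bad$sample_id, bad$target))
  }
  key <- paste(df$sample_id, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop(sprintf("duplicated qPCR rows for sample '%s', target '%s'",
                 bad[1], bad[2]))
  }
  unk <- setdiff(unique(df$unit), KNOWN_QPCR_UNITS)
  if (length(unk))
    warning("unknown qPCR unit label(s): ", paste(unk, collapse = ", "))
  class(df) <- c("qpcr_panel", "data.frame")
  df
}

#' Query a qPCR quantity
#'
#' @param panel a `qpcr_panel`.
#' @param sample,target labels.
#' @return the measured quantity, or `NA` when the pair was not assayed
#'   ("not detected/absent" — distinct from a measured 0).
#' @export
qpcr_quantity <- function(panel, sample, target) {
  i <- which(panel$sample_id == sample & panel$target == target)
  if (!length(i)) return(NA_real_)
  panel$quantity[i]
}

#' Detection status of a qPCR target in a sample
#'
#' @inheritParams qpcr_quantity
#' @return `"detected"` when a row exists, `"absent"` otherwise.
#' @export
qpcr_detection <- function(panel, sample, target) {
  if (is.na(qpcr_quantity(panel, sample, target))) "absent" else "detected"
}

#' Total bacterial loads per sample
#'
#' @param panel a `qpcr_panel`.
#' @param samples sample identifiers for which loads are required.
#' @return named numeric vector of total_bacteria quantities.
#' @export
qpcr_total_loads <- function(panel, samples) {
  loads <- vapply(samples, function(s)
    qpcr_quantity(panel, s, "total_bacteria"), 0)
  if (anyNA(loads))
    stop("missing total_bacteria qPCR measurement for sample(s): ",
         paste(samples[is.na(loads)], collapse = ", "))
  loads
}
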