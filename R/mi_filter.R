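# Mutual-information OTU filter.
#
# OTU relative-abundance profiles are discretized by equal-frequency binning;
# pairwise mutual information (plug-in estimate, natural-log units) defines an
# association network. Because the plug-in MI estimator is strongly biased
# upward at small n (its value between two independent 17-sample profiles is
# essentially never below 0.01 nats), raw MI cannot be thresholded directly at
# the tau values of interest: each pairwise MI is first screened against a
# margin-preserving permutation null, Bonferroni-corrected over an OTU's
# partners. An OTU's filter score is the largest MI among its significant
# associations (0 when it has none), and tau is applied to that score.

#' MI filter configuration
#'
#' @param tau MI threshold (nats) below which an OTU is considered
#'   uninformative. Default 0.01.
#' @param candidate_taus strictly increasing thresholds for [tau_scan].
#' @param n_bins number of equal-frequency bins; `NULL` (default) uses
#'   `max(2, min(floor(sqrt(n)), floor(n/5)))` — the square-root rule capped so
#'   every marginal stratum keeps at least five samples.
#' @param score_rule `"max_pairwise"` (default) or `"mean_pairwise"`:
#'   aggregation of an OTU's significant pairwise MIs into its filter score.
#' @param abundance_prefilter_min_count OTUs whose total count across samples
#'   is below this are dropped before MI scoring. Default 10.
#' @param edge_alpha family-wise screening level; each pairwise association is
#'   tested at `edge_alpha / (m - 1)` (Bonferroni over an OTU's `m - 1`
#'   candidate partners). Set to 1 to disable screening and threshold raw MI.
#' @param n_null_perm permutations for the null MI distribution. The
#'   permutation set is derived from a fixed internal seed, so the filter is
#'   deterministic.
#' @return A `mi_filter_config` list.
#' @export
mi_filter_config <- function(tau = 0.01,
                             candidate_taus = c(0.005, 0.01, 0.02, 0.05),
                             n_bins = NULL,
                             score_rule = c("max_pairwise", "mean_pairwise"),
                             abundance_prefilter_min_count = 10,
                             edge_alpha = 0.05,
                             n_null_perm = 2000) {
  score_rule <- match.arg(score_rule)
  stopifnot(tau >= 0,
            all(diff(candidate_taus) > 0),
            is.null(n_bins) || n_bins >= 2,
            abundance_prefilter_min_count >= 0,
            edge_alpha > 0, edge_alpha <= 1,
            n_null_perm >= 100)
  structure(list(tau = tau, candidate_taus = candidate_taus, n_bins = n_bins,
                 score_rule = score_rule,
                 abundance_prefilter_min_count = abundance_prefilter_min_count,
                 edge_alpha = edge_alpha, n_null_perm = n_null_perm),
            class = "mi_filter_config")
}

default_n_bins <- function(n) max(2L, min(floor(sqrt(n)), floor(n / 5)))

#' Equal-frequency discretization
#'
#' Rank-based binning into `n_bins` classes labelled `0 .. n_bins - 1`. With
#' distinct values, bin sizes differ by at most one; tied values always share
#' a bin (so bin sizes may then be unequal and some labels unused).
#'
#' @param values numeric vector.
#' @param n_bins number of bins, `2 <= n_bins <= length(values)`.
#' @return integer vector of bin labels.
#' @export
discretize_equal_frequency <- function(values, n_bins) {
  n <- length(values)
  if (n_bins > n) stop("n_bins (", n_bins, ") exceeds vector length (", n, ")")
  if (n_bins < 2) stop("n_bins must be at least 2")
  r <- rank(values, ties.method = "min")
  as.integer(floor((r - 1) * n_bins / n))
}

#' Mutual information of two discrete label vectors
#'
#' Plug-in estimate over the empirical joint distribution, in nats:
#' `sum_xy p(x,y) log(p(x,y) / (p(x) p(y)))`.
#'
#' @param x,y equal-length vectors of discrete labels.
#' @return non-negative scalar (nats).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  xf <- match(x, sort(unique(x))) - 1L
  yf <- match(y, sort(unique(y))) - 1L
  mi_codes(xf, max(xf) + 1L, yf, max(yf) + 1L)
}

# MI for integer codes 0..(nx-1) / 0..(ny-1); hot loop of the filter
mi_codes <- function(x, nx, y, ny) {
  n <- length(x)
  pj <- tabulate(x * ny + y + 1L, nx * ny) / n
  px <- tabulate(x + 1L, nx) / n
  py <- tabulate(y + 1L, ny) / n
  pp <- as.vector(t(outer(px, py)))    # row-major to match x*ny + y indexing
  pos <- pj > 0
  sum(pj[pos] * log(pj[pos] / pp[pos]))
}

# shared, fixed-seed permutation set; makes the screen deterministic
null_permutations <- function(n, n_perm) {
  runif(1)  # ensure .Random.seed exists
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(20260923L)
  matrix(replicate(n_perm, sample.int(n)), nrow = n)
}

#' Per-OTU MI scores and the pairwise MI matrix
#'
#' Computes the pairwise plug-in MI matrix of discretized relative-abundance
#' profiles, screens each pair against its margin-preserving permutation null
#' at level `edge_alpha / (m - 1)`, and aggregates each OTU's significant MIs
#' into a filter score by `score_rule` (an OTU with no significant association
#' scores 0).
#'
#' @param table a [count_table] (profiles are converted to relative abundance).
#' @param config a [mi_filter_config].
#' @return list with `scores` (named per-OTU), `mi` (m x m matrix),
#'   `significant` (logical m x m), `n_bins`, `edge_alpha_pair`.
#' @export
otu_mi_scores <- function(table, config = mi_filter_config()) {
  counts <- table$counts
  if (ncol(counts) < 2) stop("need at least 2 OTUs to score")
  if (nrow(counts) < 3) stop("need at least 3 samples to score")
  n <- nrow(counts); m <- ncol(counts)
  nb <- if (is.null(config$n_bins)) default_n_bins(n) else config$n_bins
  rel <- counts / rowSums(counts)
  D <- apply(rel, 2, discretize_equal_frequency, n_bins = nb)
  alpha_pair <- if (config$edge_alpha >= 1) 1 else
    min(1, config$edge_alpha / (m - 1))

  MI <- matrix(0, m, m, dimnames = list(colnames(counts), colnames(counts)))
  SIG <- matrix(FALSE, m, m, dimnames = dimnames(MI))
  perms <- if (alpha_pair < 1) null_permutations(n, config$n_null_perm)
  # null MI depends on the pair's margins only: cache per margin-signature pair
  sig_of <- function(v) paste(sort(tabulate(v + 1L, nb)), collapse = ",")
  margin_sig <- apply(D, 2, sig_of)
  crit_cache <- new.env(hash = TRUE, parent = emptyenv())
  crit_for <- function(i, j) {
    key <- paste(sort(c(margin_sig[i], margin_sig[j])), collapse = "|")
    q <- crit_cache[[key]]
    if (!is.null(q)) return(q)
    x <- D[, i]; y <- D[, j]
    nv <- vapply(seq_len(ncol(perms)),
                 function(k) mi_codes(x, nb, y[perms[, k]], nb), 0)
    q <- stats::quantile(nv, 1 - alpha_pair, names = FALSE, type = 8)
    crit_cache[[key]] <- q
    q
  }
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      v <- mi_codes(D[, i], nb, D[, j], nb)
      MI[i, j] <- MI[j, i] <- v
      s <- if (alpha_pair >= 1) TRUE else v > crit_for(i, j)
      SIG[i, j] <- SIG[j, i] <- s
    }
  }
  scores <- vapply(seq_len(m), function(i) {
    v <- MI[i, SIG[i, ]]
    if (!length(v)) return(0)
    if (config$score_rule == "max_pairwise") max(v) else mean(v)
  }, 0)
  names(scores) <- colnames(counts)
  list(scores = scores, mi = MI, significant = SIG, n_bins = nb,
       edge_alpha_pair = alpha_pair)
}

#' Threshold scan for the MI filter
#'
#' For each candidate tau: the number of OTUs whose filter score reaches tau
#' and the cumulative relative abundance they represent (relative to the
#' post-prefilter table).
#'
#' @inheritParams otu_mi_scores
#' @return data frame with columns `tau`, `n_retained`,
#'   `cumulative_relative_abundance_retained`.
#' @export
tau_scan <- function(table, config = mi_filter_config()) {
  pre <- abundance_prefilter(table, config$abundance_prefilter_min_count)
  sc <- otu_mi_scores(pre$table, config)$scores
  mass <- colSums(pre$table$counts)
  rows <- lapply(config$candidate_taus, function(tau) {
    keep <- sc >= tau
    data.frame(tau = tau, n_retained = sum(keep),
               cumulative_relative_abundance_retained =
                 sum(mass[keep]) / sum(mass))
  })
  do.call(rbind, rows)
}

abundance_prefilter <- function(table, min_count) {
  tot <- colSums(table$counts)
  keep <- tot >= min_count
  if (!any(keep)) stop("abundance prefilter removed every OTU")
  list(table = count_table(table$counts[, keep, drop = FALSE]),
       removed = colnames(table$counts)[!keep])
}

#' Apply the MI filter to an OTU table
#'
#' Drops OTUs below the abundance prefilter, scores the remainder by
#' [otu_mi_scores], retains OTUs with score `>= tau` (ties at tau retained),
#' and accounts for the read mass removed.
#'
#' @inheritParams otu_mi_scores
#' @return list with `table` (filtered [count_table]) and `report`, a
#'   `mi_filter_report` containing `retained_otu_ids`, `removed_otu_ids`,
#'   `scores`, `scan` (the [tau_scan] rows), `information_loss_percent`
#'   (percent of total read mass removed, prefilter included),
#'   `network_edges` (significant pairs with MI >= tau) and `n_bins`.
#' @export
apply_mi_filter <- function(table, config = mi_filter_config()) {
  pre <- abundance_prefilter(table, config$abundance_prefilter_min_count)
  ms <- otu_mi_scores(pre$table, config)
  keep <- ms$scores >= config$tau
  if (!any(keep))
    stop("MI filter at tau = ", config$tau,
         " removed every OTU; consider a lower tau")
  retained <- names(ms$scores)[keep]
  removed <- c(pre$removed, names(ms$scores)[!keep])
  total_mass <- sum(table$counts)
  retained_mass <- sum(table$counts[, retained, drop = FALSE])
  loss <- 100 * (1 - retained_mass / total_mass)

  up <- upper.tri(ms$mi)
  edge_keep <- up & ms$significant & ms$mi >= config$tau
  idx <- which(edge_keep, arr.ind = TRUE)
  edges <- data.frame(otu_i = rownames(ms$mi)[idx[, 1]],
                      otu_j = colnames(ms$mi)[idx[, 2]],
                      mi = ms$mi[edge_keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$mi, edges$otu_i, edges$otu_j), ]
  rownames(edges) <- NULL

  report <- structure(list(
    retained_otu_ids = retained,
    removed_otu_ids = removed,
    scores = ms$scores,
    scan = tau_scan_from_scores(ms$scores, pre$table, config),
    information_loss_percent = loss,
    network_edges = edges,
    n_bins = ms$n_bins,
    tau = config$tau), class = "mi_filter_report")
  list(table = count_table(table$counts[, retained, drop = FALSE]),
       report = report)
}

tau_scan_from_scores <- function(scores, pre_table, config) {
  mass <- colSums(pre_table$counts)
  do.call(rbind, lapply(config$candidate_taus, function(tau) {
    keep <- scores >= tau
    data.frame(tau = tau, n_retained = sum(keep),
               cumulative_relative_abundance_retained =
                 sum(mass[keep]) / sum(mass))
  }))
}

#' @export
print.mi_filter_report <- function(x, ...) {
  cat(sprintf(paste0("mi_filter_report: %d retained, %d removed ",
                     "(tau = %g, %d bins); information loss %.2f%%\n"),
              length(x$retained_otu_ids), length(x$removed_otu_ids),
              x$tau, x$n_bins, x$information_loss_percent))
  invisible(x)
}
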