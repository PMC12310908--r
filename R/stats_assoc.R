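# Association layer: rank correlations with FDR control, regressions,
# medoid clustering of the ordination, and group location tests.

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to input order and capped
#' at 1 (delegates to `stats::p.adjust`, which implements exactly this).
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return vector of q-values, same order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman correlations between functional scores and diversity metrics
#'
#' Spearman's rho (average ranks for ties) between every functional category
#' and every alpha-diversity metric, with Benjamini-Hochberg control applied
#' separately within each diversity metric's family of categories. Pairs with
#' a constant member are flagged (`NA` coefficient) and excluded from their
#' BH family.
#'
#' @param scores a `score_table`.
#' @param alpha data frame from [alpha_diversity].
#' @param use_raw correlate raw scores (default) or predicted score values.
#' @return data frame `category`, `metric`, `rho`, `p_value`, `q_value`,
#'   `flagged`.
#' @export
spearman_fdr <- function(scores, alpha, use_raw = TRUE) {
  sm <- if (use_raw) scores$raw else scores$predicted_score_value
  metrics <- setdiff(names(alpha), "sample_id")
  idx <- match(rownames(sm), alpha$sample_id)
  if (anyNA(idx)) stop("alpha profiles missing for sample(s): ",
                       paste(rownames(sm)[is.na(idx)], collapse = ", "))
  if (nrow(sm) < 4) stop("need at least 4 paired samples")
  out <- list()
  for (met in metrics) {
    y <- alpha[[met]][idx]
    rows <- lapply(colnames(sm), function(cat) {
      x <- sm[, cat]
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(data.frame(category = cat, metric = met, rho = NA_real_,
                          p_value = NA_real_, flagged = TRUE))
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
      # the asymptotic t approximation underflows to 0 at |rho| = 1
      data.frame(category = cat, metric = met,
                 rho = unname(ct$estimate),
                 p_value = max(ct$p.value, .Machine$double.xmin),
                 flagged = FALSE)
    })
    fam <- do.call(rbind, rows)
    fam$q_value <- NA_real_
    ok <- !fam$flagged
    if (any(ok)) fam$q_value[ok] <- benjamini_hochberg(fam$p_value[ok])
    out[[met]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("category", "metric", "rho", "p_value", "q_value", "flagged")]
}

tau_b <- function(x, y) {
  n <- length(x)
  cx <- outer(x, x, "-"); cy <- outer(y, y, "-")
  up <- upper.tri(cx)
  s <- sum(sign(cx[up]) * sign(cy[up]))
  tx <- sum(sign(cx[up]) != 0); ty <- sum(sign(cy[up]) != 0)
  den <- sqrt(tx * ty)
  if (den == 0) return(NA_real_)
  s / den
}

#' Kendall rank correlation with small-n exact permutation p-value
#'
#' Tie-corrected tau-b. For n <= 7 the two-sided p-value is computed by full
#' enumeration of all n! permutations of `y`; above that, the tie-corrected
#' normal approximation of `stats::cor.test` is used.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list `tau`, `p_value`, `method`, `flagged` (TRUE when a vector is
#'   all-tied and tau is undefined).
#' @export
kendall_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  t_obs <- tau_b(x, y)
  if (is.na(t_obs))
    return(list(tau = NA_real_, p_value = NA_real_,
                method = "undefined (constant vector)", flagged = TRUE))
  if (n <= 7) {
    perms <- all_permutations(n)
    tp <- vapply(seq_len(ncol(perms)), function(k) tau_b(x, y[perms[, k]]), 0)
    p <- mean(abs(tp) >= abs(t_obs) - 1e-12)
    return(list(tau = t_obs, p_value = p,
                method = "exact permutation", flagged = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(tau = t_obs, p_value = ct$p.value,
       method = "normal approximation", flagged = FALSE)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(i) {
    rbind(rep(i, ncol(sub)), sub + (sub >= i))
  }))
}

#' Regress functional scores on the alpha-diversity indices
#'
#' Ordinary least squares of each category's score on the five indices
#' (Shannon, Gini-Simpson, richness, Chao1, Zahl-Shannon) jointly.
#'
#' @param alpha data frame from [alpha_diversity].
#' @param scores a `score_table`.
#' @param use_raw regress raw scores (default) or predicted score values.
#' @return data frame `category`, `term`, `estimate`, `std_error`,
#'   `t_statistic`, `p_value`, plus per-category `r_squared`.
#' @export
diversity_function_regression <- function(alpha, scores, use_raw = TRUE) {
  sm <- if (use_raw) scores$raw else scores$predicted_score_value
  idx <- match(rownames(sm), alpha$sample_id)
  if (anyNA(idx)) stop("alpha profiles missing for some samples")
  X <- alpha[idx, c("shannon", "simpson", "richness", "chao1", "zahl_shannon")]
  if (nrow(X) <= ncol(X) + 1)
    stop("need more samples (", nrow(X), ") than predictors (", ncol(X), ")")
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  out <- lapply(colnames(sm), function(cat) {
    fit <- stats::lm(sm[, cat] ~ ., data = X)
    cf <- summary(fit)$coefficients
    data.frame(category = cat, term = rownames(cf),
               estimate = cf[, 1], std_error = cf[, 2],
               t_statistic = cf[, 3], p_value = cf[, 4],
               r_squared = summary(fit)$r.squared,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare functional profiles across ordination clusters
#'
#' Partitions the samples by partitioning-around-medoids (PAM, deterministic
#' build + swap) on the Bray-Curtis matrix into `k` clusters, then tests each
#' functional category across clusters with Kruskal-Wallis, BH-adjusted within
#' the category family.
#'
#' @param d Bray-Curtis dissimilarity matrix (samples x samples).
#' @param scores a `score_table` over the same samples.
#' @param k number of clusters (default 3; must satisfy `2 <= k < n`).
#' @param use_raw test raw scores (default) or predicted score values.
#' @return list with `cluster_labels` (named), `medoids`, and `tests`
#'   (data frame `category`, `statistic`, `p_value`, `q_value`).
#' @export
cluster_function_test <- function(d, scores, k = 3, use_raw = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 2) stop("k must be at least 2")
  if (k >= n)
    stop("k = ", k, " leaves no within-cluster replication with n = ", n,
         " samples; the across-cluster test is undefined")
  pm <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  labels <- pm$clustering
  sm <- if (use_raw) scores$raw else scores$predicted_score_value
  idx <- match(rownames(sm), rownames(d))
  if (anyNA(idx)) stop("score samples missing from the dissimilarity matrix")
  g <- factor(labels[idx])
  tests <- do.call(rbind, lapply(colnames(sm), function(cat) {
    kt <- stats::kruskal.test(sm[, cat], g)
    data.frame(category = cat, statistic = unname(kt$statistic),
               p_value = kt$p.value, stringsAsFactors = FALSE)
  }))
  tests$q_value <- benjamini_hochberg(tests$p_value)
  list(cluster_labels = labels, medoids = pm$medoids, tests = tests, k = k)
}

#' Mood's median test for two groups
#'
#' Classifies values as above vs not-above the pooled median and tests the
#' resulting 2x2 table: chi-square without continuity correction, or Fisher's
#' exact test when any expected cell count is below 5.
#'
#' @param x numeric vector of measurements.
#' @param groups two-level factor/character of the same length.
#' @return list `statistic` (chi-square, `NA` for the Fisher branch),
#'   `p_value`, `method`, `table`, `flagged` (TRUE for the degenerate case
#'   where no value exceeds the pooled median).
#' @export
median_test <- function(x, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("median test expects exactly two groups")
  med <- stats::median(x)
  above <- x > med
  tab <- table(above, droplevels(groups))
  if (nrow(tab) < 2)
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "degenerate (all values on one side of the median)",
                table = tab, flagged = TRUE))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                method = "Fisher exact", table = tab, flagged = FALSE))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       method = "chi-square", table = tab, flagged = FALSE)
}
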