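# Rarefaction, alpha diversity, Bray-Curtis / PCoA / PERMANOVA.
#
# Shannon and the Zahl jackknife estimator are reported in nats throughout.
# Standard estimators are delegated to vegan; the classic Chao1 form and the
# Zahl jackknife (not available in installed packages in the required form)
# are implemented here.

with_seed <- function(seed, expr) {
  runif(1)  # ensure .Random.seed exists
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples every sample without replacement to exactly `depth` reads
#' (single draw, reproducible under `seed`).
#'
#' @param table a [count_table].
#' @param depth target depth; must not exceed any sample's total.
#' @param seed integer seed.
#' @return A rarefied [count_table]. OTUs left with zero counts everywhere
#'   are retained (so tables stay comparable across seeds).
#' @export
rarefy <- function(table, depth, seed) {
  counts <- table$counts
  rs <- rowSums(counts)
  if (any(rs < depth))
    stop("rarefaction depth ", depth, " exceeds total reads of sample(s): ",
         paste(rownames(counts)[rs < depth], collapse = ", "))
  out <- withCallingHandlers(
    with_seed(seed, vegan::rrarefy(counts, depth)),
    warning = function(w) {
      # vegan advises against non-count input by inspecting the minimum
      # nonzero entry; deep 16S tables trip it spuriously
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(counts = out), class = "count_table")
}

chao1 <- function(x) {
  x <- x[x > 0]
  s <- length(x)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f1 == 0) return(s)
  if (f2 == 0) return(s + f1 * (f1 - 1) / 2)   # bias-corrected fallback
  s + f1^2 / (2 * f2)
}

shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# Zahl (1977) jackknife Shannon: n*H - ((n-1)/n) * sum_i H_(-i),
# with the n leave-one-individual-out terms grouped by species (O(S)).
zahl_shannon <- function(x) {
  x <- x[x > 0]
  n <- sum(x)
  if (n <= 1 || length(x) == 1) return(0)
  h <- shannon(x)
  h_minus <- vapply(seq_along(x), function(s) {
    y <- x; y[s] <- y[s] - 1
    shannon(y)
  }, 0)
  n * h - ((n - 1) / n) * sum(x * h_minus)
}

#' Alpha diversity profile per sample
#'
#' Shannon entropy (nats), Gini-Simpson (`1 - sum p^2`), observed richness,
#' classic Chao1 (`S + F1^2 / (2 F2)`; `S + F1 (F1 - 1) / 2` when no
#' doubletons exist) and the Zahl jackknife Shannon estimator.
#'
#' @param table a [count_table].
#' @return data frame with one row per sample: `sample_id`, `shannon`,
#'   `simpson`, `richness`, `chao1`, `zahl_shannon`.
#' @export
alpha_diversity <- function(table) {
  counts <- table$counts
  if (any(rowSums(counts) == 0)) stop("empty sample in alpha_diversity")
  data.frame(
    sample_id = rownames(counts),
    shannon = unname(vegan::diversity(counts, index = "shannon")),
    simpson = unname(vegan::diversity(counts, index = "simpson")),
    richness = unname(rowSums(counts > 0)),
    chao1 = unname(apply(counts, 1, chao1)),
    zahl_shannon = unname(apply(counts, 1, zahl_shannon)),
    stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` on the table's values
#' (counts or abundances).
#'
#' @param table a [count_table] or `abundance_table`.
#' @return symmetric matrix with zero diagonal, values in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  v <- values_of(table)
  if (nrow(v) < 2) stop("need at least 2 samples")
  as.matrix(vegan::vegdist(v, method = "bray"))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centers `-d^2 / 2` and eigen-decomposes it. Axes are ordered by
#' eigenvalue; axes with negative eigenvalues are reported but carry no
#' coordinates.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes number of coordinate axes requested.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   including any negative ones) and `negative_eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  n_axes <- min(n_axes, n - 1)
  cs <- stats::cmdscale(stats::as.dist(d), k = n_axes, eig = TRUE)
  eig <- cs$eig
  coords <- cs$points
  if (!is.null(coords) && ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       negative_eigenvalues = eig[eig < -1e-8 * max(abs(eig))])
}

#' PERMANOVA on a dissimilarity matrix
#'
#' One-factor permutational multivariate ANOVA: pseudo-F from the
#' among/within partition of squared dissimilarities, with
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)` under free permutation of
#' sample labels.
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups group label per sample (at least two groups).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return list with `pseudo_f`, `p_value`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("PERMANOVA needs at least two groups")
  if (n_perm < 99) stop("use at least 99 permutations")
  df <- data.frame(grp = groups)
  fit <- with_seed(seed,
    vegan::adonis2(stats::as.dist(d) ~ grp, data = df,
                   permutations = n_perm))
  list(pseudo_f = fit$F[1], p_value = fit$`Pr(>F)`[1],
       n_permutations = n_perm)
}
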