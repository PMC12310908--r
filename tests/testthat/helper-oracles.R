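# Independent brute-force oracles and small fixture builders.

# joint-histogram MI by explicit nested loops (independent of mi_codes)
brute_mi <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  s <- 0
  for (a in ux) for (b in uy) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      px <- sum(x == a) / n
      py <- sum(y == b) / n
      s <- s + pxy * log(pxy / (px * py))
    }
  }
  s
}

shannon_of <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# Zahl jackknife by direct leave-one-individual-out enumeration
brute_zahl <- function(counts) {
  counts <- counts[counts > 0]
  inds <- rep(seq_along(counts), counts)
  n <- length(inds)
  h <- shannon_of(counts)
  hm <- vapply(seq_len(n), function(i) {
    y <- counts
    y[inds[i]] <- y[inds[i]] - 1
    shannon_of(y)
  }, 0)
  n * h - ((n - 1) / n) * sum(hm)
}

# all permutations of 1..n by inserting n at every position (independent of
# the package's construction)
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Kendall tau-b by explicit pair loop
brute_tau_b <- function(x, y) {
  n <- length(x)
  s <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    s <- s + dx * dy
    tx <- tx + (dx != 0); ty <- ty + (dy != 0)
  }
  if (tx == 0 || ty == 0) return(NA_real_)
  s / sqrt(tx * ty)
}

# small deterministic count table; keeps existing dimnames unless overridden
toy_table <- function(m, samples = NULL, otus = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% rownames(m) %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- otus %||% colnames(m) %||% paste0("OTU", seq_len(ncol(m)))
  count_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_table <- function(seed, n_samples, n_otus, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus)
  m[rowSums(m) == 0, 1] <- 1
  toy_table(m)
}
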