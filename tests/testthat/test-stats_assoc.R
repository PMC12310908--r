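test_that("Benjamini-Hochberg reproduces the step-up arithmetic", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  # order-independence and monotonicity
  p <- c(0.5, 0.01, 0.03, 0.02)
  q <- benjamini_hochberg(p)
  expect_equal(q[order(p)], sort(q))
  expect_error(benjamini_hochberg(c(0.1, 0)), "0, 1")
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "0, 1")
})

test_that("Spearman layer handles monotone, anti-monotone and constant pairs", {
  alpha <- data.frame(sample_id = paste0("S", 1:6),
                      shannon = c(1, 2, 3, 4, 5, 6),
                      simpson = c(6, 5, 4, 3, 2, 1) / 10,
                      richness = c(2, 2, 2, 2, 2, 2),
                      chao1 = c(3, 1, 4, 1, 5, 9),
                      zahl_shannon = c(1.1, 2.2, 3.1, 4.9, 5.2, 6.8))
  raw <- matrix(c(10, 20, 30, 40, 50, 60,
                  2.5, 2.1, 1.7, 1.2, 0.8, 0.1), 6, 2,
                dimnames = list(alpha$sample_id, c("up", "down")))
  st <- structure(list(raw = raw), class = "score_table")
  res <- spearman_fdr(st, alpha)
  up_sh <- res[res$category == "up" & res$metric == "shannon", ]
  expect_equal(up_sh$rho, 1)
  down_sh <- res[res$category == "down" & res$metric == "shannon", ]
  expect_equal(down_sh$rho, -1)
  expect_true(all(res$flagged[res$metric == "richness"]))
  expect_true(all(is.na(res$q_value[res$metric == "richness"])))
  ok <- !res$flagged
  expect_true(all(res$q_value[ok] >= res$p_value[ok] - 1e-12))

  # rho equals the hand-ranked brute force with tie correction on a 6-point toy
  x <- c(3, 1, 4, 1, 5, 9); y <- c(2, 7, 1, 8, 2, 8)
  rho_hand <- stats::cor(rank(x), rank(y))
  st2 <- structure(list(raw = matrix(x, 6, 1,
    dimnames = list(alpha$sample_id, "f"))), class = "score_table")
  alpha2 <- alpha; alpha2$shannon <- y
  res2 <- spearman_fdr(st2, alpha2)
  expect_equal(res2$rho[res2$metric == "shannon"], rho_hand, tolerance = 1e-12)
})

test_that("Kendall tau-b and its exact p match full enumeration at n = 5", {
  expect_equal(kendall_test(1:5, c(2, 4, 6, 8, 10))$tau, 1)
  expect_equal(kendall_test(1:5, 5:1)$tau, -1)
  expect_true(kendall_test(c(1, 1, 1), c(2, 3, 4))$flagged)

  x <- c(3, 1, 4, 1, 5); y <- c(9, 2, 6, 5, 3)
  res <- kendall_test(x, y)
  expect_equal(res$tau, brute_tau_b(x, y), tolerance = 1e-12)
  perms <- perms_of(5L)
  taus <- vapply(perms, function(p) brute_tau_b(x, y[p]), 0)
  p_exact <- mean(abs(taus) >= abs(brute_tau_b(x, y)) - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  expect_identical(res$method, "exact permutation")
  # invariance under strictly monotone transforms
  expect_equal(kendall_test(exp(x), y^3)$tau, res$tau)
  # larger n: tie-corrected normal approximation
  set.seed(1)
  xx <- rnorm(12); yy <- rnorm(12)
  rn <- kendall_test(xx, yy)
  expect_identical(rn$method, "normal approximation")
  expect_equal(rn$tau, brute_tau_b(xx, yy), tolerance = 1e-12)
})

test_that("regression layer recovers exact coefficients and flags collinearity", {
  set.seed(9)
  alpha <- data.frame(sample_id = paste0("S", 1:12),
                      shannon = rnorm(12, 2), simpson = runif(12),
                      richness = rpois(12, 50), chao1 = rpois(12, 60),
                      zahl_shannon = rnorm(12, 2))
  y <- 2 * alpha$shannon + 5   # noiseless construction
  st <- structure(list(raw = matrix(y, 12, 1,
    dimnames = list(alpha$sample_id, "f"))), class = "score_table")
  res <- suppressWarnings(diversity_function_regression(alpha, st))
  expect_equal(res$estimate[res$term == "shannon"], 2, tolerance = 1e-8)
  others <- res$estimate[!res$term %in% c("(Intercept)", "shannon")]
  expect_equal(others, rep(0, 4), tolerance = 1e-8)

  # normal-equation oracle on a 7-sample toy
  a7 <- alpha[1:7, ]
  y7 <- rnorm(7)
  st7 <- structure(list(raw = matrix(y7, 7, 1,
    dimnames = list(a7$sample_id, "f"))), class = "score_table")
  r7 <- diversity_function_regression(a7, st7)
  X <- cbind(1, as.matrix(a7[, c("shannon", "simpson", "richness",
                                 "chao1", "zahl_shannon")]))
  beta <- solve(t(X) %*% X, t(X) %*% y7)
  expect_equal(r7$estimate, unname(drop(beta)), tolerance = 1e-8)

  bad <- alpha; bad$chao1 <- bad$richness * 2
  expect_error(diversity_function_regression(bad, st), "collinear")
  expect_error(diversity_function_regression(alpha[1:5, ],
    structure(list(raw = matrix(1:5, 5, 1,
      dimnames = list(alpha$sample_id[1:5], "f"))), class = "score_table")),
    "more samples")
})

test_that("cluster-function test finds planted profile differences", {
  set.seed(14)
  n <- 15
  cl_true <- rep(1:3, each = 5)
  base <- matrix(rpois(n * 8, 30), n, 8)
  base[cl_true == 2, 1:3] <- base[cl_true == 2, 1:3] + 300
  base[cl_true == 3, 4:6] <- base[cl_true == 3, 4:6] + 300
  ct <- toy_table(base)
  d <- bray_curtis(ct)
  raw <- matrix(rnorm(n * 3, 100, 2), n, 3,
                dimnames = list(sample_ids(ct), c("diff1", "diff2", "same")))
  raw[cl_true == 2, "diff1"] <- raw[cl_true == 2, "diff1"] + 50
  raw[cl_true == 3, "diff2"] <- raw[cl_true == 3, "diff2"] + 50
  st <- structure(list(raw = raw), class = "score_table")
  res <- cluster_function_test(d, st, k = 3)
  expect_length(res$cluster_labels, n)
  # PAM recovers the planted partition
  expect_equal(length(unique(paste(res$cluster_labels, cl_true))), 3)
  tq <- res$tests
  expect_lt(tq$q_value[tq$category == "diff1"], 0.05)
  expect_lt(tq$q_value[tq$category == "diff2"], 0.05)
  expect_gt(tq$q_value[tq$category == "same"], 0.05)
  expect_error(cluster_function_test(d, st, k = n), "undefined")
})

test_that("median test matches the hand-built contingency table", {
  # identical groups: no evidence
  res0 <- median_test(c(1, 2, 3, 4, 1, 2, 3, 4), rep(c("a", "b"), each = 4))
  expect_gt(res0$p_value, 0.9)
  # fully separated groups, n = 8 + 8
  res1 <- median_test(c(1:8, 101:108), rep(c("a", "b"), each = 8))
  expect_lt(res1$p_value, 0.01)
  # hand-built 10-value toy against the chi-square branch
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  g <- rep(c("a", "b"), 5)
  res2 <- median_test(x, g)
  tab <- table(x > median(x), g)
  expect_equal(unclass(res2$table), unclass(tab), ignore_attr = TRUE)
  expect_true(median_test(rep(5, 6), rep(c("a", "b"), 3))$flagged)
  expect_error(median_test(1:6, rep("a", 6)), "two groups")
})
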