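test_that("equal-frequency discretization bins by rank with ties shared", {
  expect_equal(discretize_equal_frequency(c(1, 2, 3, 4), 2), c(0L, 0L, 1L, 1L))
  expect_equal(discretize_equal_frequency(c(3, 1, 4, 2), 2), c(1L, 0L, 1L, 0L))
  expect_equal(discretize_equal_frequency(c(5, 5, 5, 5), 4), rep(0L, 4))
  # balanced bins on distinct values
  set.seed(1)
  x <- rnorm(17)
  b <- discretize_equal_frequency(x, 3)
  expect_lte(diff(range(tabulate(b + 1L, 3))), 1)
  expect_error(discretize_equal_frequency(1:3, 4), "exceeds")
})

test_that("mutual information matches closed forms and the brute-force oracle", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)), log(2))
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # hand-computed joint histogram: 0.25 ln2 + 0.25 ln(2/3) + 0.5 ln(4/3)
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 1, 1)),
               0.25 * log(2) + 0.25 * log(2 / 3) + 0.5 * log(4 / 3),
               tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "equal length")

  set.seed(42)
  for (rep in 1:20) {
    x <- sample(0:3, 15, replace = TRUE)
    y <- sample(0:2, 15, replace = TRUE)
    v <- mutual_information(x, y)
    expect_equal(v, brute_mi(x, y), tolerance = 1e-12)
    expect_gte(v, -1e-12)
    expect_equal(v, mutual_information(y, x), tolerance = 1e-12)
    expect_equal(mutual_information(x, x), shannon_of(table(x)),
                 tolerance = 1e-12)
  }
})

test_that("per-OTU scores follow association semantics", {
  # two identical profiles: score = profile entropy (their mutual MI);
  # D fills each sample to a fixed total so C is constant in relative terms
  a <- c(10, 20, 30, 40, 55, 5)
  m <- cbind(A = a, B = a, C = rep(100, 6), D = 1000 - 100 - 2 * a)
  ct <- toy_table(m)
  cfg <- mi_filter_config(edge_alpha = 1, n_bins = 2,
                          abundance_prefilter_min_count = 0)
  sc <- otu_mi_scores(ct, cfg)
  expect_equal(unname(sc$scores["A"]), log(2), tolerance = 1e-12)
  expect_equal(unname(sc$scores["B"]), log(2), tolerance = 1e-12)
  # constant profile: zero MI with everything
  expect_equal(unname(sc$mi["C", "A"]), 0, tolerance = 1e-12)

  # 5-OTU toy: scores equal exhaustive pairwise enumeration
  tab <- random_table(7, n_samples = 12, n_otus = 5)
  sc2 <- otu_mi_scores(tab, mi_filter_config(edge_alpha = 1, n_bins = 3,
                                             abundance_prefilter_min_count = 0))
  rel <- tab$counts / rowSums(tab$counts)
  D <- apply(rel, 2, discretize_equal_frequency, n_bins = 3)
  for (i in 1:5) {
    mis <- vapply(setdiff(1:5, i), function(j) brute_mi(D[, i], D[, j]), 0)
    expect_equal(unname(sc2$scores[i]), max(mis), tolerance = 1e-12)
  }

  expect_error(otu_mi_scores(toy_table(matrix(1:4, 4, 1))), "2 OTUs")
})

test_that("tau scan is monotone and hits its boundary cases", {
  tab <- random_table(11, n_samples = 10, n_otus = 8)
  cfg <- mi_filter_config(candidate_taus = c(0, 0.005, 0.02, 10),
                          abundance_prefilter_min_count = 0)
  scan <- tau_scan(tab, cfg)
  expect_equal(scan$n_retained[1], 8)   # tau = 0 retains everything
  expect_equal(scan$cumulative_relative_abundance_retained[1], 1.0)
  expect_equal(scan$n_retained[4], 0)   # tau above any score
  expect_equal(scan$cumulative_relative_abundance_retained[4], 0)
  for (seed in 1:5) {
    s <- tau_scan(random_table(seed, 9, 6), cfg)
    expect_true(all(diff(s$n_retained) <= 0))
    expect_true(all(diff(s$cumulative_relative_abundance_retained) <= 1e-12))
  }
})

test_that("filter report accounts exactly for removed read mass", {
  study <- generate_study(study_design(seed = 3))
  res <- apply_mi_filter(study$table)
  rep <- res$report
  expect_setequal(c(rep$retained_otu_ids, rep$removed_otu_ids),
                  otu_ids(study$table))
  expect_length(intersect(rep$retained_otu_ids, rep$removed_otu_ids), 0)
  retained_pct <- 100 * sum(study$table$counts[, rep$retained_otu_ids]) /
    sum(study$table$counts)
  expect_equal(rep$information_loss_percent + retained_pct, 100)
  expect_true(all(rep$network_edges$mi >= 0.01))
  # filtered table holds exactly the retained OTUs
  expect_setequal(otu_ids(res$table), rep$retained_otu_ids)
})

test_that("a mono-dominant constant-elsewhere OTU is removed and its mass lost", {
  # dominant OTU present only in one sample: no informative association
  set.seed(5)
  a <- round(exp(rnorm(9, 5, 1))) + 1
  m <- cbind(dom = c(9000, rep(0, 8)),
             a = a,
             b = round(a * exp(rnorm(9, 0, 0.05))) + 1,  # informative pair
             c = round(exp(rnorm(9, 5, 1))) + 1)
  ct <- toy_table(m)
  res <- apply_mi_filter(ct, mi_filter_config(abundance_prefilter_min_count = 0))
  expect_false("dom" %in% res$report$retained_otu_ids)
  expect_equal(res$report$information_loss_percent,
               100 * sum(m[, !colnames(m) %in% res$report$retained_otu_ids]) /
                 sum(m),
               tolerance = 1e-9)
  # removing everything errors with advice
  expect_error(
    apply_mi_filter(toy_table(matrix(c(5, 5, 5, 7, 7, 7), 3, 2)),
                    mi_filter_config(tau = 5,
                                     abundance_prefilter_min_count = 0)),
    "lower tau")
})

test_that("MI filter separates planted structure from noise across seeds", {
  hits <- vapply(4:6, function(seed) {
    study <- generate_study(study_design(seed = seed))
    res <- apply_mi_filter(study$table)
    cls <- study$truth$otu_class
    ret <- res$report$retained_otu_ids
    c(mean(!names(cls)[cls == "independent-noise"] %in% ret),
      mean(names(cls)[cls == "correlated-noise"] %in% ret))
  }, numeric(2))
  expect_gte(mean(hits[1, ]), 0.9)   # noise removed
  expect_gte(mean(hits[2, ]), 0.9)   # planted associations kept
})
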