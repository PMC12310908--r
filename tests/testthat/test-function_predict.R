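test_that("packaged capacity fixture has the expected shape and totals", {
  cap <- load_capacity_fixture()
  expect_equal(dim(cap), c(10, 12))
  expect_identical(colnames(cap), pathway_classes())
  rs <- rowSums(cap)
  expect_equal(unname(rs["Enterobacter"]), 3525)
  expect_equal(unname(rs["Bacillus"]), 2162)
  expect_equal(unname(rs["Enterococcus"]), 1823)
  expect_true(all(cap >= 0))
})

test_that("functional scores are abundance-weighted capacity sums", {
  cap <- load_capacity_fixture()
  ra <- abundance_table(
    matrix(c(1, 0, 0.5, 0,
             0, 0, 0.5, 1),
           nrow = 4,
           dimnames = list(c("only_bacillus", "zero", "mix", "only_ent"),
                           c("Bacillus", "Enterobacter")))[
             c(1, 3, 4), , drop = FALSE])
  sc <- functional_scores(ra, cap)
  expect_equal(unname(sc$total_score["only_bacillus"]), 2162)
  expect_equal(unname(sc$total_score["mix"]), (2162 + 3525) / 2)
  expect_equal(unname(sc$total_score["only_ent"]), 3525)
  expect_equal(unname(rowSums(sc$predicted_score_value)), rep(100, 3),
               tolerance = 1e-9)
  # per-category raw score of a pure sample equals the capacity row
  expect_equal(unname(sc$raw["only_bacillus", ]), unname(cap["Bacillus", ]))
})

test_that("all-zero samples are flagged, unmatched taxa reported", {
  cap <- load_capacity_fixture()
  ra <- structure(list(values = matrix(
    c(0, 0, 0.4, 0.6), nrow = 2, byrow = TRUE,
    dimnames = list(c("dead", "live"), c("Bacillus", "UnknownGenus"))),
    mode = "relative_fraction"), class = "abundance_table")
  sc <- functional_scores(ra, cap)
  expect_true(sc$flagged["dead"])
  expect_true(all(is.na(sc$predicted_score_value["dead", ])))
  expect_identical(sc$skipped, "UnknownGenus")
  expect_error(functional_scores(
    structure(list(values = matrix(1, 1, 1, dimnames = list("s", "Nobody")),
                   mode = "relative_fraction"), class = "abundance_table"),
    cap), "no abundance taxon")
})

test_that("functional scores are linear in relative abundance", {
  cap <- load_capacity_fixture()
  mk <- function(w) abundance_table(matrix(w, 1,
    dimnames = list("s", c("Weissella", "Gilliamella", "Lactococcus"))))
  a <- c(0.7, 0.2, 0.1); b <- c(0.1, 0.3, 0.6)
  for (al in c(0.25, 0.5, 0.9)) {
    mix <- functional_scores(mk(al * a + (1 - al) * b), cap)$raw
    sep <- al * functional_scores(mk(a), cap)$raw +
      (1 - al) * functional_scores(mk(b), cap)$raw
    expect_equal(mix, sep, tolerance = 1e-12)
  }
  # total lies within the range of the genera present
  sc <- functional_scores(mk(a), cap)
  rs <- rowSums(cap)[c("Weissella", "Gilliamella", "Lactococcus")]
  expect_gte(sc$total_score, min(rs))
  expect_lte(sc$total_score, max(rs))
})

test_that("EC ranking is deterministic with string tie-breaks", {
  ecs <- c("1.1.1.1", "2.6.1.1", "3.4.11.4")
  cap <- capacity_matrix(matrix(c(3, 3, 1), 1,
                                dimnames = list("Weissella", ecs)))
  ra <- abundance_table(matrix(1, 1, dimnames = list("s", "Weissella")))
  res <- ec_scores(ra, cap, k = 10)
  expect_equal(nrow(res$top), 3)          # k > categories: no padding
  expect_equal(res$top$ec, c("1.1.1.1", "2.6.1.1", "3.4.11.4"))
  expect_equal(res$top$rank, 1:3)
  bad <- capacity_matrix(matrix(1, 1, dimnames = list("g", "EC-oops")))
  expect_error(ec_scores(ra, bad), "malformed EC")

  # ranking equals an exhaustive sort oracle on random tables
  gen <- generate_ec_capacity(c("Weissella", "Bacillus"), 12, seed = 5)
  ra2 <- abundance_table(matrix(c(0.3, 0.7), 1,
    dimnames = list("s", c("Weissella", "Bacillus"))))
  res2 <- ec_scores(ra2, gen$capacity, k = 5)
  manual <- drop(ra2$values %*% gen$capacity)
  ord <- order(-manual, names(manual))[1:5]
  expect_equal(res2$top$ec, names(manual)[ord])
  expect_equal(res2$top$raw_score, unname(manual[ord]))
})

test_that("EC-to-pathway aggregation conserves mass through the fan-out", {
  raw <- matrix(c(2, 3, 5), 1, dimnames = list("s",
    c("1.1.1.1", "2.2.2.2", "3.3.3.3")))
  st <- structure(list(raw = raw), class = "score_table")
  map <- data.frame(ec = c("1.1.1.1", "1.1.1.1", "2.2.2.2"),
                    pathway_id = c("pwA", "pwB", "pwA"))
  agg <- aggregate_ec_to_pathways(st, map)
  expect_equal(unname(agg$raw["s", "pwA"]), 2 + 3)
  expect_equal(unname(agg$raw["s", "pwB"]), 2)       # full score to each pathway
  expect_equal(unname(agg$raw["s", "unmapped"]), 5)
  fanout <- c(2, 1, 0)  # links per EC; unmapped counts once
  expect_equal(sum(agg$raw), sum(raw * pmax(fanout, 1)))

  empty <- aggregate_ec_to_pathways(st, map[0, ])
  expect_equal(unname(empty$raw[, "unmapped"]), sum(raw))

  # generator fixtures: map covers every emitted EC, totals conserved
  gen <- generate_ec_capacity(c("A", "B", "C"), 9, seed = 2)
  expect_true(all(colnames(gen$capacity) %in% gen$map$ec))
  ra <- abundance_table(matrix(c(0.2, 0.5, 0.3), 1,
                               dimnames = list("s", c("A", "B", "C"))))
  sc <- functional_scores(ra, gen$capacity)
  agg2 <- aggregate_ec_to_pathways(sc, gen$map)
  fan <- table(factor(gen$map$ec, levels = colnames(gen$capacity)))
  expect_equal(sum(agg2$raw), sum(t(sc$raw) * pmax(as.vector(fan), 1)),
               tolerance = 1e-9)
})
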