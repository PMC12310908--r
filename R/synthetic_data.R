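# Synthetic study generator with known ground truth.
#
# Emulates a 17-beetle gut amplicon survey: three compositional clusters of
# samples, 17 planted core OTUs drawn from ten known gut genera, correlated
# satellite OTUs that track a core taxon but drop out of its poorest samples
# (detection-limit censoring), independent transient OTUs, one mono-dominant
# dysbiotic sample, log-normal qPCR total loads and sparse pathogen
# detections.

CORE_GENUS_POOL <- c("Apilactobacillus", "Bacillus", "Carnobacterium",
                     "Enterobacter", "Enterococcus", "Gilliamella",
                     "Lactobacillus", "Lactococcus", "Staphylococcus",
                     "Weissella")

#' Synthetic study design
#'
#' Defaults encode the emulated study conditions: 17 samples with read depths
#' in 29,611..102,067, 17 core taxa over the ten-genus pool, a dysbiotic
#' sample dominated at 99.1\% by a Spiroplasma OTU, log-normal total loads
#' (median 1e7 copies/gut, sdlog 1), Nosema detected in every sample and
#' Serratia in 6 of 17.
#'
#' @param n_samples number of samples.
#' @param depth_range integer read-depth range (min, max).
#' @param n_core_taxa planted core OTUs.
#' @param n_correlated_noise satellite OTUs tracking a core parent.
#' @param n_independent_noise transient OTUs with independent profiles.
#' @param cluster_sizes sample counts of the three planted composition
#'   clusters (must sum to `n_samples`).
#' @param cluster_contrast log-scale between-cluster offset magnitude.
#' @param within_sdlog within-cluster log-normal noise.
#' @param base_sdlog spread of core-taxon base scales.
#' @param child_sdlog multiplicative noise of satellite profiles.
#' @param child_censor number of lowest samples censored to zero per
#'   satellite (guarantees prevalence below the core cutoff).
#' @param noise_sdlog spread of independent transient profiles.
#' @param noise_censor_range per-transient censoring range (lowest samples).
#' @param mass_shares community mass fractions (core, correlated, independent).
#' @param dysbiotic_samples list of `list(sample =, taxon =, dominance =)`;
#'   the default plants "Spiroplasma" at 0.991 in sample 1, which also
#'   receives the floor read depth (the shallow mono-dominant library).
#' @param qpcr_load_median,qpcr_load_sdlog log-normal total bacterial load.
#' @param pathogen_prevalence named detection fractions for qPCR pathogens.
#' @param seed integer seed; all randomness derives from it.
#' @param max_retries redraw attempts for the core-constraint verification.
#' @return A `study_design` list.
#' @export
study_design <- function(n_samples = 17,
                         depth_range = c(29611, 102067),
                         n_core_taxa = 17,
                         n_correlated_noise = 20,
                         n_independent_noise = 25,
                         cluster_sizes = c(6, 6, 5),
                         cluster_contrast = 2.5,
                         within_sdlog = 0.2,
                         base_sdlog = 1.0,
                         child_sdlog = 0.15,
                         child_censor = 4,
                         noise_sdlog = 1.75,
                         noise_censor_range = c(4, 9),
                         mass_shares = c(core = 0.95, correlated = 0.035,
                                         independent = 0.015),
                         dysbiotic_samples = list(
                           list(sample = 1, taxon = "Spiroplasma",
                                dominance = 0.991)),
                         qpcr_load_median = 1e7,
                         qpcr_load_sdlog = 1,
                         pathogen_prevalence = c(Nosema = 1.0,
                                                 Serratia = 6 / 17),
                         seed = 1,
                         max_retries = 100) {
  stopifnot(sum(cluster_sizes) == n_samples,
            depth_range[1] <= depth_range[2],
            n_core_taxa >= 1,
            all(vapply(dysbiotic_samples,
                       function(d) d$dominance > 0 && d$dominance <= 1, TRUE)),
            all(pathogen_prevalence >= 0), all(pathogen_prevalence <= 1))
  structure(as.list(environment()), class = "study_design")
}

# 17 core OTUs over the 10-genus pool, mirroring the strain structure of the
# emulated study (3 Enterobacter, 2 Gilliamella, 3 Enterococcus species,
# 2 Weissella, singles elsewhere, one family-level Enterobacteriaceae OTU).
core_taxonomy_plan <- function(n_core) {
  plan <- data.frame(
    genus = c("Enterobacter", "Enterobacter", "Enterobacter",
              "Gilliamella", "Gilliamella",
              "Enterococcus", "Enterococcus", "Enterococcus",
              "Weissella", "Weissella",
              "Lactobacillus", "Lactococcus", "Staphylococcus",
              "Bacillus", "Carnobacterium", "Apilactobacillus", NA),
    species = c("hormaechei", NA, NA, "apicola", NA, "durans", "faecium",
                "mundtii", rep(NA, 9)),
    stringsAsFactors = FALSE)
  if (n_core <= nrow(plan)) return(plan[seq_len(n_core), ])
  extra <- data.frame(
    genus = CORE_GENUS_POOL[(seq_len(n_core - nrow(plan)) - 1) %%
                              length(CORE_GENUS_POOL) + 1],
    species = NA, stringsAsFactors = FALSE)
  rbind(plan, extra)
}

lineage_string <- function(genus = NA, species = NA, family = NA) {
  fam <- if (!is.na(family)) family else
    if (!is.na(genus)) paste0(genus, "aceae_family") else NA
  parts <- c("k__Bacteria", "p__Bacteria_phylum", "c__Bacteria_class",
             "o__Bacteria_order",
             if (!is.na(fam)) paste0("f__", fam),
             if (!is.na(genus)) paste0("g__", genus),
             if (!is.na(species)) paste0("s__", species))
  paste(parts, collapse = ";")
}

#' Generate a synthetic beetle-gut study
#'
#' Draws the community described by the design, samples counts by per-sample
#' multinomials at the drawn depths, and verifies post hoc that every planted
#' core OTU meets the core criteria in the realized table (prevalence >=
#' ceiling(0.8 n) samples and mean relative abundance >= 0.01\%) while every
#' non-core OTU fails them; the draw is repeated (up to `max_retries`) until
#' the advertised ground truth holds.
#'
#' @param design a [study_design].
#' @return list with `table` ([count_table]), `taxonomy` (`taxonomy_table`),
#'   `qpcr` (`qpcr_panel`) and `truth` (list: `core_ids`, `otu_class`,
#'   `parent`, `cluster_labels`, `qpcr_loads`, `depths`).
#' @export
generate_study <- function(design = study_design()) {
  set.seed(design$seed)
  for (attempt in seq_len(design$max_retries)) {
    out <- draw_study(design)
    if (verify_truth(out, design)) return(out)
  }
  stop("could not satisfy the planted core constraints in ",
       design$max_retries, " draws; the design is infeasible")
}

draw_study <- function(design) {
  n <- design$n_samples
  nc <- design$n_core_taxa
  nch <- design$n_correlated_noise
  nns <- design$n_independent_noise
  cl <- sample(rep(seq_along(design$cluster_sizes), design$cluster_sizes))

  core_ids <- sprintf("OTU_core_%02d", seq_len(nc))
  child_ids <- sprintf("OTU_sat_%02d", seq_len(nch))
  noise_ids <- sprintf("OTU_trans_%02d", seq_len(nns))
  dys <- design$dysbiotic_samples
  dom_ids <- vapply(seq_along(dys),
                    function(i) sprintf("OTU_dom_%s", dys[[i]]$taxon), "")
  ids <- c(core_ids, child_ids, noise_ids, dom_ids)

  W <- matrix(0, n, length(ids), dimnames = list(sprintf("P%d", seq_len(n)), ids))
  base <- exp(rnorm(nc, 0, design$base_sdlog))
  for (t in seq_len(nc)) {
    cm <- sample(c(-1, 0, 1) * design$cluster_contrast) + rnorm(3, 0, 0.2)
    W[, core_ids[t]] <- base[t] *
      exp(cm[cl] + rnorm(n, 0, design$within_sdlog))
  }
  parent <- sample(core_ids, nch, replace = TRUE)
  for (j in seq_len(nch)) {
    y <- W[, parent[j]] * exp(rnorm(n, 0, design$child_sdlog))
    y[order(y)[seq_len(design$child_censor)]] <- 0
    W[, child_ids[j]] <- y
  }
  for (j in seq_len(nns)) {
    y <- exp(rnorm(n, 0, design$noise_sdlog))
    ncen <- sample(seq(design$noise_censor_range[1],
                       design$noise_censor_range[2]), 1)
    y[order(y)[seq_len(ncen)]] <- 0
    W[, noise_ids[j]] <- y
  }
  blocks <- list(core_ids, child_ids, noise_ids)
  for (b in seq_along(blocks)) {
    msum <- mean(rowSums(W[, blocks[[b]], drop = FALSE]))
    W[, blocks[[b]]] <- W[, blocks[[b]]] / msum * design$mass_shares[b]
  }
  W <- W / rowSums(W)

  depths <- round(runif(n, design$depth_range[1], design$depth_range[2]))
  for (i in seq_along(dys)) {
    s <- dys[[i]]$sample
    W[s, ] <- W[s, ] * (1 - dys[[i]]$dominance)
    W[s, dom_ids[i]] <- dys[[i]]$dominance
    depths[s] <- design$depth_range[1]   # the shallow mono-dominant library
  }
  X <- t(vapply(seq_len(n), function(s) rmultinom(1, depths[s], W[s, ])[, 1],
                numeric(length(ids))))
  dimnames(X) <- dimnames(W)

  plan <- core_taxonomy_plan(nc)
  noise_genera <- paste0("TransientGenus", seq_len(nns))
  lineages <- c(
    vapply(seq_len(nc), function(i) {
      if (is.na(plan$genus[i]))
        lineage_string(family = "Enterobacteriaceae")
      else lineage_string(plan$genus[i], plan$species[i])
    }, ""),
    vapply(seq_len(nch), function(i)
      lineage_string(family = paste0("SatelliteFamily", i)), ""),
    vapply(seq_len(nns), function(i) lineage_string(noise_genera[i]), ""),
    vapply(seq_along(dys), function(i)
      lineage_string(dys[[i]]$taxon), ""))
  taxonomy <- taxonomy_table(ids, lineages)

  loads <- design$qpcr_load_median * exp(rnorm(n, 0, design$qpcr_load_sdlog))
  samples <- rownames(X)
  rows <- data.frame(sample = samples, target = "total_bacteria",
                     quantity = loads, unit = "16S copies/gut")
  for (pg in names(design$pathogen_prevalence)) {
    k <- round(design$pathogen_prevalence[[pg]] * n)
    hit <- sample(samples, k)
    unit <- if (pg == "Nosema") "spores/gut" else
      if (pg == "Serratia") "luxS copies/gut" else "copies/gut"
    rows <- rbind(rows, data.frame(
      sample = hit, target = pg,
      quantity = exp(rnorm(k, log(1e4), 1.5)), unit = unit))
  }
  spiro_q <- 1e3 * exp(rnorm(n, 0, 1))
  for (i in seq_along(dys))
    spiro_q[dys[[i]]$sample] <- loads[dys[[i]]$sample] * dys[[i]]$dominance
  rows <- rbind(rows, data.frame(sample = samples, target = "Spiroplasma",
                                 quantity = spiro_q, unit = "copies/gut"))
  panel <- qpcr_panel(rows$sample, rows$target, rows$quantity, rows$unit)

  cls <- c(rep("core", nc), rep("correlated-noise", nch),
           rep("independent-noise", nns), rep("dominant", length(dys)))
  names(cls) <- ids
  list(table = count_table(X), taxonomy = taxonomy, qpcr = panel,
       truth = list(core_ids = core_ids,
                    otu_class = cls,
                    parent = stats::setNames(parent, child_ids),
                    cluster_labels = stats::setNames(cl, samples),
                    qpcr_loads = stats::setNames(loads, samples),
                    depths = stats::setNames(depths, samples)))
}

verify_truth <- function(out, design) {
  res <- detect_core(out$table,
                     criteria = core_criteria(prevalence_min = 0.80,
                                              mean_rel_abundance_min = 1e-4))
  setequal(res$core_ids, out$truth$core_ids)
}

#' Generate a synthetic genus x EC capacity table and EC-to-pathway map
#'
#' Sparse Poisson enzyme counts per genus, with a consistent map in which
#' every emitted EC links to 1-3 synthetic pathways.
#'
#' @param genera character vector of genus labels.
#' @param n_ec number of EC columns (>= 1).
#' @param seed integer seed.
#' @return list with `capacity` (a `capacity_matrix` over ECs) and `map`
#'   (data frame `ec`, `pathway_id` covering every emitted EC).
#' @export
generate_ec_capacity <- function(genera, n_ec, seed = 1) {
  stopifnot(n_ec >= 1)
  with_seed(seed, {
    ecs <- unique(sprintf("%d.%d.%d.%d",
                          sample(1:6, n_ec * 3, TRUE),
                          sample(1:9, n_ec * 3, TRUE),
                          sample(1:9, n_ec * 3, TRUE),
                          sample(1:99, n_ec * 3, TRUE)))[seq_len(n_ec)]
    m <- matrix(rpois(length(genera) * n_ec, 1.2) *
                  rbinom(length(genera) * n_ec, 1, 0.6),
                nrow = length(genera),
                dimnames = list(genera, ecs))
    n_pw <- max(2, ceiling(n_ec / 2))
    pws <- sprintf("pwy_%03d", seq_len(n_pw))
    map <- do.call(rbind, lapply(ecs, function(e) {
      data.frame(ec = e, pathway_id = sample(pws, sample(1:3, 1)),
                 stringsAsFactors = FALSE)
    }))
    list(capacity = capacity_matrix(m), map = map)
  })
}
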