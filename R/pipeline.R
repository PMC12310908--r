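# End-to-end orchestration: filter -> core -> diversity -> function ->
# associations, from a single validated config, persisting every intermediate
# and a provenance manifest.

#' Build a validated pipeline configuration
#'
#' Every study default is encoded here and overridable: tau = 0.01,
#' prevalence >= 0.80, mean relative abundance >= 0.01\%, k = 3 ordination
#' clusters, 999 permutations.
#'
#' @param count_table path to the OTU table, or a [count_table].
#' @param taxonomy path or `taxonomy_table`.
#' @param qpcr optional path or `qpcr_panel` (enables absolute abundance).
#' @param out_dir output directory (created if needed).
#' @param mi a [mi_filter_config].
#' @param core a [core_criteria].
#' @param rarefy_depth `"min"` (dataset minimum) or an integer depth;
#'   `NULL` disables rarefaction before diversity.
#' @param seed integer seed for every stochastic stage.
#' @param k_clusters clusters for the ordination-function comparison.
#' @param n_perm PERMANOVA permutations.
#' @param ec_capacity optional `capacity_matrix` over ECs.
#' @param ec_map optional data frame `ec`, `pathway_id`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(count_table, taxonomy, qpcr = NULL,
                            out_dir = "beetlegut_results",
                            mi = mi_filter_config(),
                            core = core_criteria(),
                            rarefy_depth = "min",
                            seed = 42,
                            k_clusters = 3,
                            n_perm = 999,
                            ec_capacity = NULL,
                            ec_map = NULL) {
  for (p in list(count_table, taxonomy, qpcr)) {
    if (is.character(p) && !file.exists(p)) stop("no such file: ", p)
  }
  structure(list(count_table = count_table, taxonomy = taxonomy, qpcr = qpcr,
                 out_dir = out_dir, mi = mi, core = core,
                 rarefy_depth = rarefy_depth, seed = seed,
                 k_clusters = k_clusters, n_perm = n_perm,
                 ec_capacity = ec_capacity, ec_map = ec_map),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `count_table`, `taxonomy`, `qpcr`, `out_dir`, `seed`,
#' `k_clusters`, `n_perm`, `rarefy_depth`, and nested `mi` / `core` blocks
#' whose entries are passed to [mi_filter_config] / [core_criteria].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("mi", "core"))]
  args$mi <- do.call(mi_filter_config, as.list(y$mi))
  args$core <- do.call(core_criteria, as.list(y$core))
  do.call(pipeline_config, args)
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

file_checksum <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline
#'
#' Stage order: read/validate -> MI filter -> core detection -> (optional
#' absolute abundance) -> rarefaction + diversity -> functional scores ->
#' associations. Every intermediate is written to `out_dir` in standard
#' formats; a failure in stage k preserves the outputs of stages before k and
#' reports the failing stage.
#'
#' @param config a `pipeline_config` (or path to a YAML config).
#' @return A `run_manifest`: list with per-stage status, output paths and
#'   checksums, the package version and the seed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("beetlegut")),
                   seed = config$seed, stages = list(), warnings = character())
  out <- function(f) file.path(config$out_dir, f)
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      status = "ok", outputs = files,
      checksums = vapply(files, file_checksum, ""))
    stage_log(stage, paste("ok ->", paste(basename(files), collapse = ", ")))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- input
  tab <- run_stage("input", {
    tab <- if (inherits(config$count_table, "count_table")) config$count_table
      else read_count_table(config$count_table)
    stage_log("input", sprintf("%d samples x %d OTUs",
                               nrow(tab$counts), ncol(tab$counts)))
    tab
  })
  taxonomy <- run_stage("input", {
    if (inherits(config$taxonomy, "taxonomy_table")) config$taxonomy
    else read_taxonomy(config$taxonomy, table = tab)
  })
  panel <- run_stage("input", {
    if (is.null(config$qpcr)) NULL
    else if (inherits(config$qpcr, "qpcr_panel")) config$qpcr
    else read_qpcr_panel(config$qpcr)
  })
  manifest$stages[["input"]] <- list(status = "ok")

  # -- MI filter
  filt <- run_stage("filter_mi", {
    res <- apply_mi_filter(tab, config$mi)
    write_table(res$table, out("filtered_table.tsv"))
    write_table(data.frame(otu_id = names(res$report$scores),
                           mi_score = res$report$scores,
                           retained = names(res$report$scores) %in%
                             res$report$retained_otu_ids),
                out("mi_report.tsv"))
    write_table(res$report$scan, out("tau_scan.tsv"))
    write_table(res$report$network_edges, out("network_edges.tsv"))
    stage_log("filter_mi", sprintf(
      "%d -> %d OTUs, information loss %.2f%%",
      ncol(tab$counts), ncol(res$table$counts),
      res$report$information_loss_percent))
    record("filter_mi", out(c("filtered_table.tsv", "mi_report.tsv",
                              "tau_scan.tsv", "network_edges.tsv")))
    res
  })

  # -- core detection
  core <- run_stage("core", {
    res <- detect_core(filt$table, taxonomy, config$core)
    write_table(res$summary, out("core_result.tsv"))
    write_table(res$summary[, c("taxon", "prevalence", "mean_rel_abundance")],
                out("prevalence_abundance_points.tsv"))
    record("core", out(c("core_result.tsv",
                         "prevalence_abundance_points.tsv")))
    res
  })

  # -- absolute abundance
  if (!is.null(panel)) {
    run_stage("absolute_abundance", {
      abs_tab <- to_absolute(to_relative(filt$table), panel)
      write_table(abs_tab, out("absolute_abundance.tsv"))
      record("absolute_abundance", out("absolute_abundance.tsv"))
    })
  }

  # -- diversity
  div <- run_stage("diversity", {
    dt <- filt$table
    if (!is.null(config$rarefy_depth)) {
      depth <- if (identical(config$rarefy_depth, "min"))
        min(rowSums(dt$counts)) else config$rarefy_depth
      dt <- rarefy(dt, depth, seed = config$seed)
      stage_log("diversity", sprintf("rarefied to %d reads/sample", depth))
    }
    alpha <- alpha_diversity(dt)
    bc <- bray_curtis(dt)
    ord <- pcoa(bc, n_axes = 2)
    write_table(alpha, out("alpha.tsv"))
    write_table(data.frame(sample_id = rownames(bc), bc,
                           check.names = FALSE), out("bray_curtis.tsv"))
    write_table(data.frame(sample_id = rownames(ord$coordinates),
                           ord$coordinates, check.names = FALSE),
                out("pcoa_coords.tsv"))
    record("diversity", out(c("alpha.tsv", "bray_curtis.tsv",
                              "pcoa_coords.tsv")))
    list(alpha = alpha, bc = bc, ord = ord)
  })

  # -- functional prediction
  fun <- run_stage("function", {
    cap <- load_capacity_fixture()
    core_ra <- core_genus_abundance(filt$table, taxonomy, core)
    sc <- functional_scores(core_ra, cap)
    write_table(sc, out("class_scores.tsv"))
    files <- out("class_scores.tsv")
    ecres <- NULL
    if (!is.null(config$ec_capacity)) {
      ecres <- ec_scores(core_ra, config$ec_capacity)
      write_table(ecres$scores, out("ec_scores.tsv"))
      files <- c(files, out("ec_scores.tsv"))
      if (!is.null(config$ec_map)) {
        pw <- aggregate_ec_to_pathways(ecres$scores, config$ec_map)
        write_table(pw, out("pathway_scores.tsv"))
        files <- c(files, out("pathway_scores.tsv"))
      }
    }
    record("function", files)
    list(scores = sc, ec = ecres)
  })
  if (length(fun$scores$skipped))
    manifest$warnings <- c(manifest$warnings,
      paste("no capacity row for:",
            paste(fun$scores$skipped, collapse = ", ")))

  # -- associations
  run_stage("associate", {
    sp <- spearman_fdr(fun$scores, div$alpha)
    reg <- diversity_function_regression(div$alpha, fun$scores)
    cf <- cluster_function_test(div$bc, fun$scores, k = config$k_clusters)
    pv <- permanova(div$bc, cf$cluster_labels, n_perm = config$n_perm,
                    seed = config$seed)
    write_table(sp, out("spearman_fdr.tsv"))
    write_table(reg, out("regressions.tsv"))
    write_table(cf$tests, out("cluster_function.tsv"))
    jsonlite::write_json(pv, out("permanova.json"), auto_unbox = TRUE,
                         digits = NA)
    record("associate", out(c("spearman_fdr.tsv", "regressions.tsv",
                              "cluster_function.tsv", "permanova.json")))
  })

  manifest$config_hash <- config_hash(config)
  class(manifest) <- "run_manifest"
  jsonlite::write_json(
    manifest_json(manifest), out("run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  manifest
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  file_checksum(tmp)
}

manifest_json <- function(m) {
  list(package_version = m$package_version, seed = m$seed,
       config_hash = m$config_hash,
       stages = lapply(m$stages, function(s)
         s[intersect(names(s), c("status", "outputs", "checksums", "error"))]),
       warnings = m$warnings)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest (beetlegut", x$package_version, ", seed", x$seed, ")\n")
  for (nm in names(x$stages))
    cat(sprintf("  %-18s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
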