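#' Assemble and validate a pipeline configuration
#'
#' One flat configuration drives the full analysis. The two library presets
#' reproduce the study conditions of the mat transect: `"16S"` rarefies to
#' 760,000 reads per sample and reports Shannon in base 2; `"ITS"` rarefies
#' to 164,820 reads and uses base e (the two amplicon libraries were
#' processed by toolchains with those conventions).
#'
#' @param table_path path to the community table TSV.
#' @param tree_path path to the Newick tree.
#' @param metadata_path optional sample metadata TSV (for the Mantel test).
#' @param taxonomy_path optional taxonomy TSV.
#' @param out_dir output directory for the result bundle.
#' @param preset `"16S"`, `"ITS"` or `"none"` (no preset defaults).
#' @param rarefaction_depth reads per sample; `NA` skips rarefaction (for
#'   tables deposited post-rarefaction).
#' @param shannon_log_base `"2"` or `"e"`.
#' @param n_null_replicates null-model replicates (default 1000).
#' @param n_mantel_permutations Mantel permutations (default 999).
#' @param ses_thresholds SES classification bound (default 2).
#' @param quartile_method quartile estimator for the rare/abundant rule.
#' @param include_root PD convention.
#' @param seed global seed; each stochastic stage runs on a documented
#'   substream (`seed + 1` rarefaction, `+ 2` Mantel, `+ 3` whole-sample
#'   SES, `+ 4` subset SES).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(table_path, tree_path, metadata_path = NULL,
                            taxonomy_path = NULL, out_dir = "results",
                            preset = c("none", "16S", "ITS"),
                            rarefaction_depth = NULL,
                            shannon_log_base = NULL,
                            n_null_replicates = 1000L,
                            n_mantel_permutations = 999L,
                            ses_thresholds = 2,
                            quartile_method = c("nearest_rank", "type7"),
                            include_root = TRUE,
                            seed = 1L) {
  preset <- match.arg(preset)
  quartile_method <- match.arg(quartile_method)
  if (is.null(rarefaction_depth))
    rarefaction_depth <- switch(preset, `16S` = 760000L, ITS = 164820L, none = NA)
  if (is.null(shannon_log_base))
    shannon_log_base <- switch(preset, `16S` = "2", ITS = "e", none = "e")
  cfg <- list(table_path = table_path, tree_path = tree_path,
              metadata_path = metadata_path, taxonomy_path = taxonomy_path,
              out_dir = out_dir, preset = preset,
              rarefaction_depth = rarefaction_depth,
              shannon_log_base = match.arg(shannon_log_base, c("e", "2")),
              n_null_replicates = as.integer(n_null_replicates),
              n_mantel_permutations = as.integer(n_mantel_permutations),
              ses_thresholds = ses_thresholds,
              quartile_method = quartile_method,
              include_root = include_root,
              seed = as.integer(seed))
  if (cfg$n_null_replicates < 2L || cfg$n_mantel_permutations < 1L ||
      cfg$ses_thresholds <= 0)
    stop("numeric pipeline parameters must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full diversity pipeline
#'
#' Stages, in order: read inputs, (optionally) rarefy, alpha diversity,
#' Bray-Curtis and Jaccard beta diversity with UPGMA dendrograms, Mantel
#' test of Jaccard and Bray-Curtis against transect distance (when metadata
#' is given), shared-ASV intersections, per-site quartile partitions,
#' relative-abundance partition, PD/PSC per sample and subset, and SES of
#' PD and PSC for whole samples and rare/abundant subsets. Every output is
#' TSV or Newick under `config$out_dir`, plus `manifest.json` recording all
#' parameters, seeds and convention flags; rerunning with the same config
#' reproduces every file byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  out <- list()

  tree <- stage("read_tree", read_tree(config$tree_path))
  tab <- stage("read_table", {
    ct <- read_community_table(config$table_path, tree = tree)
    n_off <- sum(!colnames(ct$counts) %in% tree$tip.label)
    if (n_off > 0L)
      message("  ", n_off, " table ASVs are absent from the tree ",
              "(kept for non-phylogenetic analyses)")
    ct
  })
  counts <- tab$counts

  if (!is.na(config$rarefaction_depth))
    counts <- stage("rarefy",
      rarefy(counts, config$rarefaction_depth, seed = config$seed + 1L))
  out$table <- counts

  out$alpha <- stage("alpha", alpha_diversity(counts, config$shannon_log_base))
  write_report(out$alpha, file.path(config$out_dir, "alpha_diversity.tsv"))

  out$beta <- stage("beta", {
    lapply(c(bray_curtis = "bray_curtis", jaccard = "jaccard"), function(m) {
      dmat <- beta_diversity(counts, m)
      write_distance_matrix(dmat, file.path(config$out_dir, paste0("beta_", m, ".tsv")))
      write_tree(upgma(dmat), file.path(config$out_dir, paste0("upgma_", m, ".nwk")))
      dmat
    })
  })

  if (!is.null(config$metadata_path)) {
    out$mantel <- stage("mantel", {
      meta <- read_sample_metadata(config$metadata_path)
      meta <- meta[match(rownames(counts), meta$sample_id), ]
      if (anyNA(meta$sample_id))
        stop("metadata is missing sample(s): ",
             paste(setdiff(rownames(counts), meta$sample_id), collapse = ", "))
      geo <- geographic_distances(meta)
      res <- lapply(names(out$beta), function(m)
        mantel_test(out$beta[[m]], geo,
                    n_permutations = config$n_mantel_permutations,
                    seed = config$seed + 2L))
      names(res) <- names(out$beta)
      df <- data.frame(metric = names(res),
                       r = vapply(res, `[[`, numeric(1L), "r"),
                       p = vapply(res, `[[`, numeric(1L), "p"),
                       n_permutations = vapply(res, `[[`, numeric(1L), "n_permutations"))
      write_report(df, file.path(config$out_dir, "mantel.tsv"))
      res
    })
  }

  out$intersections <- stage("core", {
    xs <- shared_intersections(counts)
    write_report(xs$subsets, file.path(config$out_dir, "intersections.tsv"))
    xs
  })

  out$partitions <- stage("partition", {
    parts <- quartile_partitions(counts, config$quartile_method)
    df <- do.call(rbind, lapply(parts, function(p) data.frame(
      sample_id = p$sample_id,
      asv_id = c(p$rare_asvs, p$abundant_asvs),
      class = rep(c("rare", "abundant"),
                  c(length(p$rare_asvs), length(p$abundant_asvs))),
      q1_threshold = p$q1_threshold, q3_threshold = p$q3_threshold,
      stringsAsFactors = FALSE)))
    write_report(df, file.path(config$out_dir, "quartile_partition.tsv"))
    parts
  })

  out$relabund <- stage("relabund", {
    ra <- relabund_partition(counts)
    write_report(data.frame(unit = names(ra$rel_abundance),
                            rel_abundance = as.numeric(ra$rel_abundance),
                            class = ifelse(names(ra$rel_abundance) %in% ra$abundant,
                                           "abundant", "rare")),
                 file.path(config$out_dir, "relabund_partition.tsv"))
    ra
  })

  ix <- stage("tree_index", phylo_edge_index(tree))

  out$phylo <- stage("phylodiv", {
    pm <- phylo_metrics(counts, ix, partitions = out$partitions,
                        include_root = config$include_root)
    write_report(pm, file.path(config$out_dir, "phylo_metrics.tsv"))
    # Table-1-shaped summary: one row per sample, metrics as columns
    wide <- out$alpha
    for (col in c("PD.all", "PD.rare", "PD.abundant", "PSC.all")) {
      parts <- strsplit(col, ".", fixed = TRUE)[[1L]]
      v <- pm$value[pm$metric == parts[1L] & pm$subset_label == parts[2L]]
      wide[[gsub(".", "_", col, fixed = TRUE)]] <-
        v[match(wide$sample_id,
                pm$sample_id[pm$metric == parts[1L] & pm$subset_label == parts[2L]])]
    }
    write_report(wide, file.path(config$out_dir, "diversity_summary.tsv"))
    pm
  })

  out$ses <- stage("ses", {
    whole <- ses_metric(counts, ix, metric = "PSC", partition = "none",
                        n_replicates = config$n_null_replicates,
                        seed = config$seed + 3L,
                        include_root = config$include_root)
    subs <- do.call(rbind, lapply(c("PD", "PSC"), function(m)
      ses_metric(counts, ix, metric = m, partition = "quartile",
                 n_replicates = config$n_null_replicates,
                 seed = config$seed + 4L,
                 quartile_method = config$quartile_method,
                 include_root = config$include_root)))
    ses <- rbind(whole, subs)
    write_report(ses, file.path(config$out_dir, "ses.tsv"))
    ses
  })

  manifest <- c(unclass(config),
                list(package_version = as.character(utils::packageVersion("rarephylo")),
                     n_samples = nrow(counts), n_asvs = ncol(counts)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out)
}
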