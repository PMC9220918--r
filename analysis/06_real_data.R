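#!/usr/bin/env Rscript
# Stage 6 (optional): the same analysis on the study's deposited ASV
# tables. The tables are not distributed with this repository; export the
# deposited 16S community composition table to TSV (samples x ASVs, a
# trailing taxonomy column is fine) as asv_table_16s.tsv, plus a
# metadata.tsv (sample_id, position_m for the 1.5-m transect), in a
# directory passed as the first argument.
#
#   Rscript analysis/06_real_data.R /path/to/real_data

library(rarephylo)

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1 || !file.exists(file.path(args[1], "asv_table_16s.tsv")))
  stop("usage: Rscript analysis/06_real_data.R <dir with asv_table_16s.tsv>")
dir <- args[1]
out <- "results/real_data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ct <- read_community_table(file.path(dir, "asv_table_16s.tsv"))
cat("table:", nrow(ct$counts), "samples x", ncol(ct$counts), "ASVs\n")

xs <- shared_intersections(ct$counts)
print(xs)
ra <- relabund_partition(ct$counts, threshold_pct = 1)
cat(sprintf(">1%%-abundant ASVs: %d (%.0f%% of reads)\n",
            length(ra$abundant), 100 * ra$read_fraction[["abundant"]]))
parts <- quartile_partitions(ct$counts)
cat("Q1 range:", range(vapply(parts, `[[`, numeric(1), "q1_threshold")),
    " Q3 range:", range(vapply(parts, `[[`, numeric(1), "q3_threshold")), "\n")

meta_path <- file.path(dir, "metadata.tsv")
if (file.exists(meta_path)) {
  meta <- read_sample_metadata(meta_path)
  meta <- meta[match(rownames(ct$counts), meta$sample_id), ]
  res <- mantel_test(beta_diversity(ct$counts, "jaccard"),
                     geographic_distances(meta),
                     n_permutations = 999, seed = 1)
  print(res)
}
write_report(xs$subsets, file.path(out, "intersections_16s.tsv"))
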