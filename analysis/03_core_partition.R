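#!/usr/bin/env Rscript
# Stage 3: shared-core quantification (UpSet-style intersection counts) and
# the two rare/abundant partitions: whole-table >1% relative abundance, and
# the per-site quartile rule.

library(rarephylo)

dat <- "results/data"
out <- "results/partition"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_community_table(file.path(dat, "asv_table.tsv"))$counts

xs <- shared_intersections(tab)
print(xs)
write_report(xs$subsets, file.path(out, "intersections.tsv"))
writeLines(xs$core_asvs, file.path(out, "core_asvs.txt"))
truth <- readLines(file.path(dat, "truth_core_asvs.txt"))
cat(sprintf("core recovers %d/%d planted core ASVs\n",
            sum(truth %in% xs$core_asvs), length(truth)))

ra <- relabund_partition(tab, threshold_pct = 1)
cat(sprintf(">1%% relative abundance: %d abundant ASVs carrying %.1f%% of reads; %d rare (%.1f%%)\n",
            length(ra$abundant), 100 * ra$read_fraction[["abundant"]],
            length(ra$rare), 100 * ra$read_fraction[["rare"]]))
write_report(data.frame(unit = names(ra$rel_abundance),
                        rel_abundance = as.numeric(ra$rel_abundance),
                        class = ifelse(names(ra$rel_abundance) %in% ra$abundant,
                                       "abundant", "rare")),
             file.path(out, "relabund_partition.tsv"))

parts <- quartile_partitions(tab)
pdf_rows <- do.call(rbind, lapply(parts, function(p) data.frame(
  sample_id = p$sample_id, q1 = p$q1_threshold, q3 = p$q3_threshold,
  n_rare = length(p$rare_asvs), n_abundant = length(p$abundant_asvs))))
print(pdf_rows, row.names = FALSE)
write_report(pdf_rows, file.path(out, "quartile_thresholds.tsv"))
write_report(do.call(rbind, lapply(parts, function(p) data.frame(
  sample_id = p$sample_id,
  asv_id = c(p$rare_asvs, p$abundant_asvs),
  class = rep(c("rare", "abundant"),
              c(length(p$rare_asvs), length(p$abundant_asvs)))))),
  file.path(out, "quartile_partition.tsv"))
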