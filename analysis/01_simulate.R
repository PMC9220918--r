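#!/usr/bin/env Rscript
# Stage 1: generate the synthetic mat-transect dataset every later stage
# consumes. The generator is calibrated to the community structure of the
# hypersaline elastic mat: 10 samples on a 1.5-m transect, a tiny (3% of
# taxa) shared core carrying ~72.5% of reads, and a long lognormal rare
# tail. One clade-placed variant is also written so the null-model stage
# has a dataset with known clustered truth.

library(rarephylo)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tree <- simulate_tree(1000, seed = 101)
mat <- simulate_communities(tree, sim_params(
  n_samples = 10, n_taxa = 1000, depth = 100000, seed = 102))
print(mat)

write_tree(tree, file.path(out, "tree.nwk"))
write_community_table(mat$table, file.path(out, "asv_table.tsv"))
writeLines(c("sample_id\tposition_m",
             paste0(rownames(mat$table), "\t", seq(0, 1.5, length.out = 10))),
           file.path(out, "metadata.tsv"))
writeLines(mat$truth$core_asvs, file.path(out, "truth_core_asvs.txt"))

# clustered-truth variant: the abundant subcommunity drawn from one clade
tree_c <- simulate_tree(300, seed = 201)
mat_c <- simulate_communities(tree_c, sim_params(
  n_samples = 10, n_taxa = 300, depth = 20000, core_size = 30,
  abundant_placement = "clade", seed = 202))
write_tree(tree_c, file.path(out, "tree_clade.nwk"))
write_community_table(mat_c$table, file.path(out, "asv_table_clade.tsv"))
writeLines(mat_c$truth$core_asvs, file.path(out, "truth_core_asvs_clade.txt"))

cat("wrote", length(list.files(out)), "files under", out, "\n")
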