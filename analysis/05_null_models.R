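#!/usr/bin/env Rscript
# Stage 5: the null-model distribution of PSC (nmdPSC): standardized effect
# sizes of PD and PSC under the richness null, for whole samples and for
# the rare/abundant quartile subcommunities, on the clade-placed dataset
# whose abundant subcommunity is clustered by construction.

library(rarephylo)

dat <- "results/data"
out <- "results/nullmodels"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tree <- read_tree(file.path(dat, "tree_clade.nwk"))
tab <- read_community_table(file.path(dat, "asv_table_clade.tsv"), tree = tree)$counts

whole <- ses_metric(tab, tree, metric = "PSC", partition = "none",
                    n_replicates = 1000, seed = 105)
subs <- do.call(rbind, lapply(c("PD", "PSC"), function(m)
  ses_metric(tab, tree, metric = m, partition = "quartile",
             n_replicates = 1000, seed = 106)))
ses <- rbind(whole, subs)
write_report(ses, file.path(out, "ses.tsv"))

nmdpsc <- ses[ses$metric == "PSC", ]
cat("nmdPSC classification (richness null, 1000 replicates, +/-2 bounds):\n")
print(table(nmdpsc$subset_label, nmdpsc$label))
ab <- nmdpsc[nmdpsc$subset_label == "abundant", ]
cat(sprintf("abundant subcommunity: %d/%d samples clustered (median SES %.2f)\n",
            sum(ab$label == "clustered"), nrow(ab), median(ab$ses)))
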