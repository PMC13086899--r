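#!/usr/bin/env Rscript
# Stage 3: phylogenetic signal per neuropil (Blomberg's K).
#
# K = 1 is the Brownian-motion expectation; the permutation test asks
# whether there is any signal at all (K = 0), the BM simulation test whether
# the signal departs from the BM expectation (K = 1). 10,000 replicates each.

library(lepibrain)

tree <- parse_newick(paste(readLines("results/data/tree.nwk"), collapse = ""))
vt <- read_volume_table("results/data/volumes.csv")
summed <- sum_paired(vt)
ref <- reference_volume(summed)
analysed <- summed[!(summed$neuropil %in%
                       c("superior", "ventrolateral", "ventromedial",
                         "inferior", "circumesophageal", "gnathal")), ]
traits <- relative_volumes(species_aggregate(analysed), ref)

st <- signal_table(traits, tree, n_perm = 10000, n_sim = 10000, seed = 1)
write.table(st, "results/signal.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d of %d neuropils show significant phylogenetic signal (K != 0)\n",
            sum(st$signif_K0, na.rm = TRUE), nrow(st)))
cat(sprintf("%d neuropils depart from the BM expectation (K != 1)\n",
            sum(st$signif_K1, na.rm = TRUE)))
cat(sprintf("Median K = %.2f\n", median(st$K, na.rm = TRUE)))
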