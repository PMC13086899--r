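#!/usr/bin/env Rscript
# Stage 6: pairwise scaling slopes and hierarchical clustering.
#
# Neuropils that scale in conjunction across the phylogeny are candidate
# functional units. All-against-all PGLS slopes on log relative volumes are
# symmetrized into an association matrix, converted to distances, and
# clustered (average linkage).

library(lepibrain)

tree <- parse_newick(paste(readLines("results/data/tree.nwk"), collapse = ""))
vt <- read_volume_table("results/data/volumes.csv")
summed <- sum_paired(vt)
ref <- reference_volume(summed)
refs <- c("superior", "ventrolateral", "ventromedial", "inferior",
          "circumesophageal", "gnathal")
traits <- relative_volumes(species_aggregate(
  summed[!(summed$neuropil %in% refs), ]), ref)
C <- vcv_matrix(tree)

sm <- pairwise_slopes(traits, C)
td <- to_distance(sm)
cl <- hcluster(td$distance, linkage = "average", k = 4)

write.table(sm$slope, "results/slope_matrix.tsv", sep = "\t", quote = FALSE)
write.table(td$distance, "results/distance_matrix.tsv", sep = "\t",
            quote = FALSE)
writeLines(cl$newick, "results/dendrogram.nwk")
write.table(data.frame(neuropil = names(cl$clusters),
                       cluster = unname(cl$clusters)),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Cluster membership at k = 4:\n")
for (k in sort(unique(cl$clusters)))
  cat(sprintf("  %d: %s\n", k,
              paste(names(cl$clusters)[cl$clusters == k], collapse = ", ")))
neg <- sum(td$association[upper.tri(td$association)] < 0)
cat(sprintf("Negative associations: %d of %d pairs\n", neg,
            sum(upper.tri(td$association))))
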