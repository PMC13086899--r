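#!/usr/bin/env Rscript
# Stage 4: allometric scaling against the reference volume, and total brain
# volume against wingspan.
#
# Each neuropil's log species-mean volume is regressed on the log reference
# volume by PGLS; the slope index si = b - 1 measures departure from
# isometry. The wingspan regression uses the dimension-matched null b0 = 3
# (volume on length).

library(lepibrain)

tree <- parse_newick(paste(readLines("results/data/tree.nwk"), collapse = ""))
vt <- read_volume_table("results/data/volumes.csv")
eco <- read_ecology_table("results/data/ecology.csv")
summed <- sum_paired(vt)
ref <- reference_volume(summed)
refs <- c("superior", "ventrolateral", "ventromedial", "inferior",
          "circumesophageal", "gnathal")
traits <- relative_volumes(species_aggregate(
  summed[!(summed$neuropil %in% refs), ]), ref)
C <- vcv_matrix(tree)

iso <- isometry_table(traits, C, b0 = 1)
write.table(iso, "results/isometry.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Neuropils with adjusted R2 > 0.6: %d of %d\n",
            sum(iso$included), nrow(iso)))
steep <- iso$neuropil[iso$included & iso$significant & iso$si > 0]
shallow <- iso$neuropil[iso$included & iso$significant & iso$si < 0]
cat("Scaling steeper than isometry:",
    if (length(steep)) paste(steep, collapse = ", ") else "none", "\n")
cat("Scaling shallower than isometry:",
    if (length(shallow)) paste(shallow, collapse = ", ") else "none", "\n")

ws <- setNames(eco$wingspan, eco$species)
wa <- wingspan_allometry(traits, ws, C, b0 = 3)
write.table(data.frame(n = wa$n, b = wa$si$b, se_b = wa$si$se_b,
                       si = wa$si$si, chisq = wa$si$chisq, p = wa$si$p,
                       r_squared = wa$fit$r_squared),
            "results/wingspan.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Brain volume ~ wingspan: b = %.2f (null 3), R2 = %.2f, p = %.3g\n",
            wa$si$b, wa$fit$r_squared, wa$si$p))
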