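#!/usr/bin/env Rscript
# Stage 5: grade-shift analyses for activity period and migratory status.
#
# For each neuropil: first test whether the two ecological groups share a
# scaling slope; where they do, compare intercepts at the common slope
# (grade-shift index gsi = a1/a2 - 1). Where slopes differ, gsi is invalid
# and the slope difference itself is the finding.

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

for (fac in c("activity", "migration")) {
  groups <- setNames(eco[[fac]], eco$species)
  tab <- grade_shift_table(traits, groups, C)
  out <- sprintf("results/gradeshift_%s.tsv", fac)
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("\n== %s (%s vs %s) ==\n", fac, tab$group1[1], tab$group2[1]))
  sd_np <- tab$neuropil[tab$slopes_differ]
  cat("Slopes differ:",
      if (length(sd_np)) paste(sd_np, collapse = ", ") else "none", "\n")
  gs <- tab[tab$gsi_valid & tab$included & tab$significant_shift, ]
  if (nrow(gs)) {
    for (i in seq_len(nrow(gs)))
      cat(sprintf("Grade shift in %s: gsi = %.2f (chi2 = %.2f, p = %.3g)\n",
                  gs$neuropil[i], gs$gsi[i], gs$chisq_intercept[i],
                  gs$p_intercept[i]))
  } else cat("No significant grade shifts\n")
}
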