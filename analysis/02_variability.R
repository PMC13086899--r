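#!/usr/bin/env Rscript
# Stage 2: check the PGLS precondition that between-species variation
# dominates within-species variation. Species means are only a meaningful
# unit of analysis if individuals of a species cluster tightly around them.

library(lepibrain)

vt <- read_volume_table("results/data/volumes.csv")
summed <- sum_paired(vt)
vr <- variability_report(summed)

dir.create("results", showWarnings = FALSE)
write.table(vr, "results/variability.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Median inter/intra dispersion ratio: %.1f (range %.1f-%.1f)\n",
            median(vr$ratio, na.rm = TRUE), min(vr$ratio, na.rm = TRUE),
            max(vr$ratio, na.rm = TRUE)))
cat(if (median(vr$ratio, na.rm = TRUE) >= 10)
  "Between-species variation exceeds within-species variation by >= 10x: species means are a sound unit of analysis.\n"
  else
    "WARNING: dispersion ratio below 10; species-mean analyses may be noisy.\n")
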