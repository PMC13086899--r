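#!/usr/bin/env Rscript
# Stage 7: robustness checks.
#
# (a) Leverage screen: does any single species dominate an isometry fit?
# (b) Two-factor PGLS: are the activity-period and migration effects
#     separable, or does one masquerade as the other?

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
logx <- log(traits$reference)

lev <- do.call(rbind, lapply(colnames(traits$mean), function(np) {
  y <- log(traits$mean[, np]); y <- y[!is.na(y)]
  fit <- pgls_fit(y, design_matrix(logx[names(y)]), C)
  cbind(neuropil = np, leverage_screen(fit))
}))
write.table(lev, "results/leverage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
flagged <- lev[lev$flagged, ]
cat(sprintf("Leverage flags: %d species-neuropil pairs", nrow(flagged)))
if (nrow(flagged))
  cat(" (", paste(unique(flagged$species), collapse = ", "), ")")
cat("\n")

activity <- setNames(eco$activity, eco$species)
migration <- setNames(eco$migration, eco$species)
tf <- do.call(rbind, lapply(colnames(traits$mean), function(np) {
  y <- log(traits$mean[, np]); y <- y[!is.na(y)]
  res <- tryCatch(two_factor_pgls(y, logx, activity, migration, C),
                  error = function(e) NULL)
  if (is.null(res)) return(NULL)
  cbind(neuropil = np, res$tests)
}))
write.table(tf, "results/two_factor.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- tf[tf$p < 0.05, ]
cat(sprintf("Two-factor model: %d of %d factor terms significant at 0.05\n",
            nrow(sig), nrow(tf)))
if (nrow(sig))
  for (i in seq_len(nrow(sig)))
    cat(sprintf("  %s / %s: chi2 = %.2f, p = %.3g\n", sig$neuropil[i],
                sig$term[i], sig$chisq[i], sig$p[i]))
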