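#!/usr/bin/env Rscript
# Step 4 — brain-behavior correlation among smokers.
#
# Mean dFC variability over each surviving cluster, correlated (Pearson)
# with smoking years, cigarettes/day and FTCD across smokers, with
# Benjamini-Hochberg FDR over all (cluster x behavior) pairs.

suppressPackageStartupMessages(library(dfcvar))

state <- readRDS("scratch/inference.rds")
map_dir <- "scratch/maps"
tab <- state$tab

maps <- lapply(tab$id, function(id) {
  as.array(RNifti::readNifti(file.path(map_dir,
                                       sprintf("%s_%s_dfcsd.nii.gz", id,
                                               state$seed_tag))))
})
feat <- extract_cluster_features(list(seed = maps), state$clusters, "seed",
                                 tab$group)
write.csv(data.frame(id = tab$id, group = tab$group, feat),
          "results/cluster_features.csv", row.names = FALSE)

sm <- tab$group == "smoker"
bb <- pearson_with_fdr(feat[sm, , drop = FALSE],
                       tab[sm, c("smoking_years", "cigs_per_day", "ftcd")])
print(bb, digits = 3)
write.csv(bb, "results/brain_behavior.csv", row.names = FALSE)
for (i in which(bb$significant))
  message(sprintf("%s vs %s: r = %.3f (p = %.4g, FDR p = %.4g) — survives FDR",
                  bb$cluster[i], bb$behavior[i], bb$r[i], bb$p[i],
                  bb$p_fdr[i]))
if (!any(bb$significant))
  message("no (cluster, behavior) pair survives FDR at q = 0.05")
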