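#!/usr/bin/env Rscript
# Stage 5: M1/M2 polarization of macrophages. Module scores are computed
# over every QC-passing singlet, species-stratified, with
# expression-bin-matched controls; the M2-vs-M1 comparison is then read
# off the macrophage subset of each species.

library(xenocensus)

data_dir <- "results/data"
out <- "results"

truth <- read.csv(file.path(data_dir, "barnyard", "truth.csv"))
cen <- readRDS("scratch/census.rds")
cfg <- read_run_config(file.path(data_dir, "run_config.yaml"))

keep <- colnames(cen$normalized)
tk <- truth[match(keep, truth$barcode), ]
singlets <- tk$barcode[!tk$is_doublet]
species <- setNames(tk$species[match(singlets, tk$barcode)], singlets)

pol <- polarization_scores(cen$normalized[, singlets], species = species,
                           n_bins = cfg$n_bins, n_ctrl = cfg$n_ctrl,
                           seed = cfg$seed)
macro <- singlets[grepl("macrophage",
                        tk$cell_type[match(singlets, tk$barcode)])]
pm <- pol[pol$barcode %in% macro, ]
cmp <- compare_polarization(pm, pm$species)
print(cmp)
cat(sprintf(
  "pooled: %.1f%% of %d macrophages score M2 above M1\n",
  100 * mean(pm$score_m2 > pm$score_m1), nrow(pm)))

write.csv(pol, file.path(out, "polarization_scores.csv"),
          row.names = FALSE)
write.csv(cmp, file.path(out, "polarization_summary.csv"),
          row.names = FALSE)
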