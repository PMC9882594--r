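#!/usr/bin/env Rscript
# Stage 4: QC filtering, normalization, variable genes, PCA/SNN
# clustering and marker genes; clusters compared against the planted cell
# types.

library(xenocensus)

data_dir <- "results/data"
out <- "results"

mat <- read_tagged_matrix(file.path(data_dir, "barnyard"))
truth <- read.csv(file.path(data_dir, "barnyard", "truth.csv"))
cfg <- read_run_config(file.path(data_dir, "run_config.yaml"))

cen <- run_census(mat, truth[, c("barcode", "doublet_score")],
                  thresholds = cfg$qc, n_hvg = cfg$n_hvg,
                  n_components = cfg$n_components,
                  k_neighbors = cfg$k_neighbors,
                  resolution = cfg$resolution, seed = cfg$seed)
print(cen$qc)
cat(sprintf("%d clusters over %d retained cells\n",
            nlevels(cen$clusters), cen$qc$n_retained_cells))

keep <- colnames(cen$qc$matrix)
tk <- truth[match(keep, truth$barcode), ]
singl <- !tk$is_doublet
tab <- table(cluster = cen$clusters[keep][singl],
             truth = tk$cell_type[singl])
print(tab)
ari <- function(t) {
  sij <- sum(choose(t, 2)); si <- sum(choose(rowSums(t), 2))
  sj <- sum(choose(colSums(t), 2)); n2 <- choose(sum(t), 2)
  e <- si * sj / n2; (sij - e) / ((si + sj) / 2 - e)
}
cat(sprintf("adjusted Rand index vs planted types: %.3f\n", ari(tab)))

write.csv(data.frame(barcode = keep, cluster = as.character(cen$clusters[keep])),
          file.path(out, "clusters.csv"), row.names = FALSE)
top_markers <- do.call(rbind, lapply(names(cen$markers), function(cl) {
  cbind(cluster = cl, head(cen$markers[[cl]], 5))
}))
write.csv(top_markers, file.path(out, "top_markers.csv"),
          row.names = FALSE)
cat("top markers per cluster written; first rows:\n")
print(head(top_markers, 10))

dir.create("scratch", showWarnings = FALSE)
saveRDS(cen, "scratch/census.rds")
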