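#!/usr/bin/env Rscript
# Stage 2: build the modified species-specific references.
#
# Each species' panel is screened against the pure sample of the opposite
# species; genes collecting more than 3 cross-mapped counts over the whole
# sample are homology artifacts and are removed from that species'
# reference.

library(xenocensus)

data_dir <- "results/data"
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pure_pig <- read_tagged_matrix(file.path(data_dir, "pure_pig"))
pure_human <- read_tagged_matrix(file.path(data_dir, "pure_human"))

cfg <- read_run_config(file.path(data_dir, "run_config.yaml"))
panels <- generator_panels(cfg$generator)

modref_human <- build_modified_reference(panels$human, pure_pig,
                                         cfg$gene_removal_threshold)
modref_pig <- build_modified_reference(panels$pig, pure_human,
                                       cfg$gene_removal_threshold)
print(modref_human)
print(modref_pig)

write_modified_reference_report(modref_human,
                                file.path(out, "removed_genes_human.csv"))
write_modified_reference_report(modref_pig,
                                file.path(out, "removed_genes_pig.csv"))
dir.create("scratch", showWarnings = FALSE)
saveRDS(list(human = modref_human, pig = modref_pig),
        "scratch/modified_references.rds")

cat(sprintf(
  "removed genes are exactly the configured homolog partners: human %s, pig %s\n",
  all(modref_human$removed$name %in% panels$homologs$human_name),
  all(modref_pig$removed$name %in% panels$homologs$pig_name)))
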