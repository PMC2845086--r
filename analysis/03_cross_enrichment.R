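#!/usr/bin/env Rscript
# The headline computation: every test-subtype contrast x every reference
# gene set, scored by phenotype-permutation GSEA (2000 permutations,
# weighted running sum), significance at FDR q <= 0.25. Exports the masked
# NES grid, the complete table, leading-edge gene lists and a manifest.

suppressPackageStartupMessages(library(crossgsea))

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
data_dir <- "results/data"
x <- read_expression(file.path(data_dir, "test_expression.gct"), "gct")
groups <- read_groups(file.path(data_dir, "test_groups.cls"), "cls",
                      samples = colnames(x))
sets <- read_gmt("results/reference_sets.gmt")

em <- run_matrix(x, groups, sets, n_perm = 2000, weight = 1,
                 q_threshold = 0.25, seed = seed)
paths <- export_matrix(em, "results", prefix = "cross")

print(em)
parts <- partition_by_direction(em)
cat(sprintf("up-side report: %d cell(s); down-side report: %d cell(s)\n",
            nrow(parts$up), nrow(parts$down)))
sig <- em$results[em$results$significant,
                  c("subtype", "set", "nes", "p", "q")]
if (nrow(sig)) {
  cat("significant enrichments:\n")
  print(sig, row.names = FALSE, digits = 3)
}
cat("exports:", paste(basename(paths), collapse = ", "), "\n")
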