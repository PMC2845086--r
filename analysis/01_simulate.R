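#!/usr/bin/env Rscript
# Generate the linked synthetic study: a leukemia-like test dataset with
# three genetic subtypes and a five-tissue reference panel, sharing a gene
# universe, with one planted 50%-overlapping up-module (first subtype <->
# first tissue). Writes GCT/CLS pairs plus the ground truth.

suppressPackageStartupMessages(library(crossgsea))
library(yaml)

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- synthetic_design(seed = seed)
sim <- generate_datasets(design)

write_expression(sim$test$x, file.path(out, "test_expression.gct"), "gct")
write_groups(sim$test$groups, file.path(out, "test_groups.cls"), "cls")
write_expression(sim$reference$x, file.path(out, "reference_expression.gct"), "gct")
write_groups(sim$reference$groups, file.path(out, "reference_groups.cls"), "cls")
write_yaml(sim$truth, file.path(out, "ground_truth.yaml"))

cat(sprintf("test: %d genes x %d samples (%d subtypes)\n",
            nrow(sim$test$x), ncol(sim$test$x), nlevels(sim$test$groups)))
cat(sprintf("reference: %d genes x %d samples (%d tissues)\n",
            nrow(sim$reference$x), ncol(sim$reference$x),
            nlevels(sim$reference$groups)))
cat(sprintf("planted overlap: %d shared genes (%s)\n",
            length(sim$truth$shared[[1]]), names(sim$truth$shared)[1]))
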