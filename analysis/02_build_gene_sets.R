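#!/usr/bin/env Rscript
# Build the up/down gene-set database from the reference panel: intensity
# floor, mean-centering, variation filter (SD >= 0.5), then per-tissue
# one-vs-rest Welch t with BH-FDR truncation at 1% (cap 300 per direction),
# and the >15/<500 size filter. Writes a GMT plus an exclusion log.

suppressPackageStartupMessages(library(crossgsea))

data_dir <- "results/data"
out <- "results"
x <- read_expression(file.path(data_dir, "reference_expression.gct"), "gct")
groups <- read_groups(file.path(data_dir, "reference_groups.cls"), "cls",
                      samples = colnames(x))

prep <- variation_filter(mean_center(floor_values(x)), sd_min = 0.5)
cat(sprintf("variation filter kept %d of %d genes\n", nrow(prep), nrow(x)))

sets <- build_gene_sets(prep, groups, fdr_max = 0.01, cap = 300)
flt <- filter_by_size(sets, 15, 500)

write_gmt(flt$sets, file.path(out, "reference_sets.gmt"))
write.table(flt$excluded, file.path(out, "excluded_sets.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("built %d gene sets (sizes %s); %d excluded by the size filter\n",
            length(flt$sets), paste(range(lengths(flt$sets)), collapse = "-"),
            nrow(flt$excluded)))
if (nrow(flt$excluded)) print(flt$excluded)
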