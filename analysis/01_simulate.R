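#!/usr/bin/env Rscript
# Generate the three synthetic datasets with planted ground truth that the
# later analysis steps consume: an F1/P1/P2 trio expression matrix, SNP
# allele counts under the six regulatory-divergence categories, and a
# 24-sample module-structured matrix with kernel traits.

library(kernelreg)

seed <- 2026L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = seed, genes_per_category = 100,
                         read_depth_per_snp = 200, n_modules = 5,
                         genes_per_module = 60, n_background_genes = 100,
                         factor_loading = 0.9, hubs_per_module = 10)

trio <- simulate_trio_expression(cfg)
write_expression_tsv(trio$expression, "results/data/trio_expression.tsv")
write.table(trio$truth, "results/data/trio_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ase <- simulate_regulatory_counts(cfg)
write_allele_counts_tsv(ase$counts, "results/data/allele_counts.tsv")
write.table(ase$truth, "results/data/regulatory_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mods <- simulate_module_expression(cfg)
write_expression_tsv(mods$expression, "results/data/module_expression.tsv")
write.table(data.frame(sample = rownames(mods$traits), mods$traits),
            "results/data/traits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(mods$truth, "results/data/module_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated at seed", seed, ":\n",
    nrow(trio$expression$values), "trio genes (4 modes x 100),\n",
    length(unique(ase$counts$gene_id)), "ASE genes (6 categories x 100),\n",
    nrow(mods$expression$values), "module-matrix genes over",
    ncol(mods$expression$values), "samples.\n")
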