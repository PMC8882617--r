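#!/usr/bin/env Rscript
# Replicate QC, sample PCA and hybrid-vs-parent differential expression on
# the simulated trio matrix. DEGs (FPKM > 1 in the larger group, FDR < 0.05,
# |log2FC| > 1) feed the inheritance step.

library(kernelreg)

expr <- read_expression_tsv("results/data/trio_expression.tsv")

qc <- do.call(rbind, lapply(c("F1", "P1", "P2"), function(g)
  cbind(genotype = g, replicate_correlation(expr, g, "S1"))))
write.table(qc, "results/replicate_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Replicate Pearson correlations:",
    sprintf("%.4f-%.4f", min(qc$r), max(qc$r)), "\n")

pca <- pca_samples(log_transform(expr))
write.table(data.frame(sample = rownames(pca$scores), pca$scores),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("PC1/PC2 variance explained:",
    sprintf("%.1f%% / %.1f%%", 100 * pca$variance_explained[1],
            100 * pca$variance_explained[2]), "\n")

deg1 <- differential_expression(expr, c("F1", "S1"), c("P1", "S1"))
deg2 <- differential_expression(expr, c("F1", "S1"), c("P2", "S1"))
write.table(deg1, "results/deg_f1_vs_p1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(deg2, "results/deg_f1_vs_p2.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
degs <- union(deg1$gene_id[deg1$passes], deg2$gene_id[deg2$passes])
writeLines(degs, "results/deg_union.txt")
cat(sum(deg1$passes), "DEGs vs P1,", sum(deg2$passes), "vs P2;",
    length(degs), "in the union.\n")
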