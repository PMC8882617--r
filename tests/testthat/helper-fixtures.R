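# Shared fixture builders; all fixtures are generated in code.

# Tiny expression matrix: genes x (genotypes x replicates), one stage.
make_expr <- function(values, genotypes, stage = "S1") {
  values <- as.matrix(values)
  nrep <- ncol(values) / length(genotypes)
  meta <- data.frame(
    sample = paste(rep(genotypes, each = nrep), stage,
                   rep(seq_len(nrep), length(genotypes)), sep = "_"),
    genotype = rep(genotypes, each = nrep),
    stage = stage,
    replicate = rep(seq_len(nrep), length(genotypes)),
    stringsAsFactors = FALSE
  )
  expression_matrix(values,
                    gene_ids = sprintf("g%03d", seq_len(nrow(values))),
                    sample_meta = meta)
}

# Long-format allele counts for one SNP of one gene, equal counts per
# replicate unless vectors are given.
make_snp_counts <- function(gene_id = "g1", pos = 100,
                            hyb_a1 = c(20, 20, 20), hyb_a2 = c(20, 20, 20),
                            p1 = c(40, 40, 40), p2 = c(40, 40, 40)) {
  nrep <- length(hyb_a1)
  data.frame(
    chrom = "chr1", pos = pos, gene_id = gene_id,
    library = rep(c("hybrid", "parent1", "parent2"), each = nrep),
    replicate = rep(seq_len(nrep), 3L),
    allele1_count = c(hyb_a1, p1, rep(0L, nrep)),
    allele2_count = c(hyb_a2, rep(0L, nrep), p2),
    stringsAsFactors = FALSE
  )
}

# Independent step-up BH oracle, straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[ord[i]] / i)
    q[ord[i]] <- min(prev, 1)
  }
  q
}
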