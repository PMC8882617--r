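test_that("site filter enforces the four retention rules", {
  good <- make_snp_counts("g1", pos = 100, hyb_a1 = c(13, 13, 13),
                          hyb_a2 = c(12, 12, 12))
  shallow <- make_snp_counts("g2", pos = 200, hyb_a1 = c(10, 13, 13),
                             hyb_a2 = c(9, 12, 12))   # one replicate at 19
  nothet <- make_snp_counts("g3", pos = 300, hyb_a1 = c(25, 25, 25),
                            hyb_a2 = c(0, 12, 12))
  badpar <- make_snp_counts("g4", pos = 400)
  badpar$allele2_count[badpar$library == "parent1" &
                       badpar$replicate == 2] <- 3  # parent 1 not homozygous
  counts <- rbind(good, shallow, nothet, badpar)
  genomic <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400))

  f <- filter_snps(counts, genomic)
  expect_setequal(unique(f$gene_id), "g1")
  log <- attr(f, "filter_log")
  expect_equal(unname(log["input"]), 4)
  expect_equal(unname(log["depth"]), 1)
  # a site absent from the genomic evidence is dropped even if counts pass
  f2 <- filter_snps(counts, data.frame(chrom = "chr1", pos = c(200, 300, 400)))
  expect_equal(nrow(f2), 0)
  # without a genomic set, rule (a) is skipped
  f3 <- filter_snps(counts, NULL)
  expect_setequal(unique(f3$gene_id), "g1")
  expect_error(filter_snps(transform(good, allele1_count = -1), NULL),
               "nonnegative")
})

test_that("allelic-imbalance chi-square matches its closed form and tail", {
  b <- test_allelic_imbalance(30, 30)
  expect_equal(b$statistic, 0)
  expect_equal(b$p_value, 1)
  u <- test_allelic_imbalance(40, 10)
  expect_equal(u$statistic, 18)   # (40-25)^2/25 + (10-25)^2/25
  # upper tail by quadrature of the df = 1 chi-square density
  dens <- function(x) exp(-x / 2) / sqrt(2 * pi * x)
  p_quad <- integrate(dens, 18, Inf, rel.tol = 1e-10)$value
  expect_equal(u$p_value, p_quad, tolerance = 1e-6)
  expect_warning(z <- test_allelic_imbalance(0, 0), "zero total")
  expect_true(is.na(z$p_value))
})

test_that("T-set ratio comparison is a symmetric pooled-variance t-test", {
  same <- test_ratio_difference(c(1, 1.2, 0.8), c(1, 1.2, 0.8))
  expect_equal(same$p_value, 1)
  r <- test_ratio_difference(c(2.0, 2.1, 1.9), c(0.0, 0.1, -0.1))
  # pooled sd 0.1, difference 2: t = 2 / (0.1 * sqrt(2/3)) = 24.4949
  expect_equal(abs(r$statistic), 2 / (0.1 * sqrt(2 / 3)), tolerance = 1e-6)
  expect_lt(r$p_value, 0.01)
  r_sw <- test_ratio_difference(c(0.0, 0.1, -0.1), c(2.0, 2.1, 1.9))
  expect_equal(r$p_value, r_sw$p_value, tolerance = 1e-12)
  expect_error(test_ratio_difference(1, c(1, 2)), "at least 2")
  flat <- test_ratio_difference(c(1, 1), c(1, 1))
  expect_equal(flat$p_value, 1)
})

test_that("the decision table is exhaustive and matches the seven criteria", {
  # independent restatement of the criteria, enumerated over all 16
  # combinations of three significance flags and the sign relation
  expected <- function(P, H, T, same_sign) {
    if (P && H && !T) return("cis-only")
    if (P && !H && T) return("trans-only")
    if (P && H && T) return(if (same_sign) "cis+trans" else "cis×trans")
    if (!P && H && T) return("compensatory")
    if (!P && !H && !T) return("conserved")
    "ambiguous"
  }
  for (P in c(TRUE, FALSE)) for (H in c(TRUE, FALSE))
    for (T in c(TRUE, FALSE)) for (same in c(TRUE, FALSE)) {
      got <- classify_regulatory_pattern(P, H, T,
                                         log2_ratio_P = if (same) 1.2 else -1.2,
                                         log2_ratio_H = 0.8)
      expect_identical(got, expected(P, H, T, same),
                       info = sprintf("P=%s H=%s T=%s same=%s", P, H, T, same))
    }
  expect_warning(
    amb <- classify_regulatory_pattern(TRUE, TRUE, TRUE, 0, 1),
    "sign undefined")
  expect_identical(amb, "ambiguous")
})

test_that("gene aggregation applies the 60% majority rule", {
  a <- aggregate_gene_pattern(c(rep("cis-only", 3), rep("trans-only", 2)))
  expect_equal(a$pattern, "cis-only")
  expect_equal(a$supporting_fraction, 0.6)
  b <- aggregate_gene_pattern("cis-only")
  expect_equal(b$pattern, "cis-only")
  expect_equal(b$supporting_fraction, 1)
  c2 <- aggregate_gene_pattern(rep(c("cis-only", "trans-only"), 2))
  expect_equal(c2$pattern, "unassigned")
  expect_equal(c2$supporting_fraction, 0.5)
  expect_error(aggregate_gene_pattern(character(0)), "at least one")
})

test_that("relabeling the alleles flips ratios but never the pattern", {
  set.seed(77)
  cfg <- simulation_config(seed = 77, genes_per_category = 5)
  sim <- simulate_regulatory_counts(cfg)
  orig <- run_ase_pipeline(sim$counts)
  swapped <- sim$counts
  # consistent relabel: swap allele columns and the parent identities
  tmp <- swapped$allele1_count
  swapped$allele1_count <- swapped$allele2_count
  swapped$allele2_count <- tmp
  swapped$library <- c(hybrid = "hybrid", parent1 = "parent2",
                       parent2 = "parent1")[swapped$library]
  flip <- run_ase_pipeline(swapped)
  m <- merge(orig$snp_calls, flip$snp_calls, by = c("chrom", "pos"))
  expect_equal(m$log2_ratio_H.x, -m$log2_ratio_H.y, tolerance = 1e-9)
  expect_equal(m$log2_ratio_P.x, -m$log2_ratio_P.y, tolerance = 1e-9)
  expect_identical(m$pattern.x, m$pattern.y)
})

test_that("empty post-filter input yields an all-zero summary", {
  empty <- make_snp_counts(hyb_a1 = c(5, 5, 5), hyb_a2 = c(5, 5, 5))
  res <- run_ase_pipeline(empty)   # depth 10 < 20 everywhere
  expect_null(res$snp_calls)
  expect_true(all(res$summary$count == 0))
})

test_that("planted categories are recovered from simulated counts", {
  cfg <- simulation_config(seed = 21, genes_per_category = 40,
                           read_depth_per_snp = 200)
  sim <- simulate_regulatory_counts(cfg)
  res <- run_ase_pipeline(sim$counts)
  m <- merge(res$gene_calls, sim$truth)
  acc <- tapply(m$pattern == m$regulatory_category, m$regulatory_category,
                mean)
  expect_true(all(acc[setdiff(names(acc), "conserved")] >= 0.8))
  expect_gte(acc["conserved"], 0.75)   # bounded by (1 - 0.05)^3
})
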