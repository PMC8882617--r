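#' @keywords internal
regulatory_patterns <- c("cis-only", "trans-only", "cis+trans", "cis×trans",
                         "compensatory", "conserved", "ambiguous")

#' Filter SNP sites for allele-specific analysis
#'
#' Retains sites that (a) are present in the genomic evidence set, (b) show
#' divergent, homozygous parental alleles in every parental replicate
#' (parent 1 carries only allele 1, parent 2 only allele 2), (c) are
#' heterozygous in every hybrid replicate (at least \code{min_het_reads} of
#' each allele), and (d) reach total depth >= \code{min_depth} in every
#' hybrid and parental replicate.
#'
#' @param counts Long-format allele-count data frame with columns
#'   \code{chrom}, \code{pos}, \code{gene_id}, \code{library} (one of
#'   \code{"hybrid"}, \code{"parent1"}, \code{"parent2"}),
#'   \code{replicate}, \code{allele1_count}, \code{allele2_count}. Allele 1
#'   always denotes the parent-1 allele.
#' @param genomic_sites Data frame of DNA-level sites with columns
#'   \code{chrom}, \code{pos} (1-based), e.g. from
#'   \code{\link{read_variants_vcf}}. \code{NULL} skips rule (a), for count
#'   tables already restricted to co-detected sites.
#' @param min_depth Minimum per-replicate total depth (default 20).
#' @param min_het_reads Minimum reads of each allele per hybrid replicate
#'   (default 1).
#' @return The filtered \code{counts} data frame, with an attribute
#'   \code{"filter_log"} giving site counts in/out of each rule.
#' @export
filter_snps <- function(counts, genomic_sites = NULL, min_depth = 20,
                        min_het_reads = 1) {
  need <- c("chrom", "pos", "gene_id", "library", "replicate",
            "allele1_count", "allele2_count")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "))
  if (any(counts$allele1_count < 0) || any(counts$allele2_count < 0) ||
      any(counts$allele1_count != round(counts$allele1_count)) ||
      any(counts$allele2_count != round(counts$allele2_count)))
    stop("allele counts must be nonnegative integers")
  key <- paste(counts$chrom, counts$pos, sep = ":")
  sites <- unique(key)
  log <- c(input = length(sites))

  if (!is.null(genomic_sites)) {
    gkey <- paste(genomic_sites$chrom, genomic_sites$pos, sep = ":")
    sites <- sites[sites %in% gkey]
  }
  log <- c(log, genomic_evidence = length(sites))

  site_ok <- function(k, test) {
    sub <- counts[key == k, , drop = FALSE]
    test(sub)
  }
  # (b) homozygous divergent parents in every replicate
  sites <- sites[vapply(sites, site_ok, logical(1L), test = function(sub) {
    p1 <- sub[sub$library == "parent1", ]
    p2 <- sub[sub$library == "parent2", ]
    nrow(p1) > 0L && nrow(p2) > 0L &&
      all(p1$allele1_count >= 1 & p1$allele2_count == 0) &&
      all(p2$allele2_count >= 1 & p2$allele1_count == 0)
  })]
  log <- c(log, parental_divergence = length(sites))

  # (c) heterozygous hybrid in every replicate
  sites <- sites[vapply(sites, site_ok, logical(1L), test = function(sub) {
    h <- sub[sub$library == "hybrid", ]
    nrow(h) > 0L && all(h$allele1_count >= min_het_reads &
                        h$allele2_count >= min_het_reads)
  })]
  log <- c(log, hybrid_heterozygous = length(sites))

  # (d) depth in every replicate of every library
  sites <- sites[vapply(sites, site_ok, logical(1L), test = function(sub) {
    all(sub$allele1_count + sub$allele2_count >= min_depth)
  })]
  log <- c(log, depth = length(sites))

  out <- counts[key %in% sites, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  out
}

#' Chi-square test of allelic imbalance against 1:1
#'
#' One-degree-of-freedom goodness-of-fit test of two pooled allele totals
#' against equality: statistic sum((obs - exp)^2 / exp) with exp =
#' (a + b) / 2 for both cells.
#'
#' @param allele1_total,allele2_total Pooled read counts.
#' @return List with \code{statistic} and \code{p_value} (upper tail,
#'   df = 1). A zero grand total yields NA for both.
#' @export
test_allelic_imbalance <- function(allele1_total, allele2_total) {
  if (allele1_total < 0 || allele2_total < 0)
    stop("allele totals must be nonnegative")
  n <- allele1_total + allele2_total
  if (n == 0) {
    warning("zero total depth; imbalance test undefined")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  e <- n / 2
  stat <- (allele1_total - e)^2 / e + (allele2_total - e)^2 / e
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' t-test comparing hybrid and parental allelic log2 ratios
#'
#' Two-tailed homoscedastic two-sample t-test between per-replicate hybrid
#' log2 allelic ratios and per-replicate parental log2 ratios (the T set).
#'
#' @param hybrid_ratios,parental_ratios Numeric vectors of per-replicate
#'   log2 ratios, at least 2 each.
#' @return List with \code{statistic} and \code{p_value}. Identical
#'   zero-variance vectors give p = 1.
#' @export
test_ratio_difference <- function(hybrid_ratios, parental_ratios) {
  if (length(hybrid_ratios) < 2L || length(parental_ratios) < 2L)
    stop("at least 2 ratios per side required")
  if (stats::sd(hybrid_ratios) == 0 && stats::sd(parental_ratios) == 0) {
    eq <- isTRUE(all.equal(mean(hybrid_ratios), mean(parental_ratios)))
    return(list(statistic = if (eq) 0 else Inf,
                p_value = if (eq) 1 else 0))
  }
  tt <- stats::t.test(hybrid_ratios, parental_ratios, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Seven-way regulatory-divergence pattern from three test outcomes
#'
#' Deterministic decision table on the significance of the parental ratio
#' test (P), the hybrid allelic-ratio test (H) and the hybrid-vs-parent
#' ratio comparison (T), plus sign agreement of the two log2 ratios:
#' \itemize{
#'   \item P, H significant, T not: cis-only
#'   \item P, T significant, H not: trans-only
#'   \item all three significant, same ratio signs: cis+trans
#'   \item all three significant, opposite signs: cis×trans
#'   \item H, T significant, P not: compensatory
#'   \item none significant: conserved
#'   \item anything else: ambiguous
#' }
#'
#' @param sig_P,sig_H,sig_T Logical significance flags (p < alpha).
#' @param log2_ratio_P,log2_ratio_H Log2 allelic ratios used for the sign
#'   comparison.
#' @return One of the seven pattern labels.
#' @export
classify_regulatory_pattern <- function(sig_P, sig_H, sig_T,
                                        log2_ratio_P, log2_ratio_H) {
  stopifnot(is.logical(sig_P), is.logical(sig_H), is.logical(sig_T))
  if (sig_P && sig_H && !sig_T) return("cis-only")
  if (sig_P && !sig_H && sig_T) return("trans-only")
  if (sig_P && sig_H && sig_T) {
    s <- sign(log2_ratio_P) * sign(log2_ratio_H)
    if (s == 0) {
      warning("zero log2 ratio with all sets significant; sign undefined")
      return("ambiguous")
    }
    return(if (s > 0) "cis+trans" else "cis×trans")
  }
  if (!sig_P && sig_H && sig_T) return("compensatory")
  if (!sig_P && !sig_H && !sig_T) return("conserved")
  "ambiguous"
}

# One SNP: pooled chi-square tests for H and P, replicate-level t-test for
# T, pattern classification. Pseudocount 0.5 on every ratio.
snp_regulatory_call <- function(hyb_a1, hyb_a2, p1_counts, p2_counts,
                                alpha = 0.05, parent_size_ratio = 1) {
  p2s <- p2_counts * parent_size_ratio   # scale P2 to P1 library size
  H <- test_allelic_imbalance(sum(hyb_a1), sum(hyb_a2))
  P <- test_allelic_imbalance(sum(p1_counts), sum(p2s))
  rh <- log2((hyb_a1 + 0.5) / (hyb_a2 + 0.5))
  rp <- log2((p1_counts + 0.5) / (p2s + 0.5))
  T <- test_ratio_difference(rh, rp)
  ratio_H <- log2((sum(hyb_a1) + 0.5) / (sum(hyb_a2) + 0.5))
  ratio_P <- log2((sum(p1_counts) + 0.5) / (sum(p2s) + 0.5))
  sig <- function(p) !is.na(p) && p < alpha
  pattern <- classify_regulatory_pattern(sig(P$p_value), sig(H$p_value),
                                         sig(T$p_value), ratio_P, ratio_H)
  list(p_P = P$p_value, p_H = H$p_value, p_T = T$p_value,
       log2_ratio_P = ratio_P, log2_ratio_H = ratio_H, pattern = pattern)
}

#' Aggregate SNP-level patterns into one gene-level call
#'
#' A gene inherits the modal SNP pattern if that pattern supports at least
#' \code{majority} of its SNPs; otherwise it stays unassigned. The
#' supporting fraction is reported either way.
#'
#' @param patterns Character vector of per-SNP pattern labels for one gene.
#' @param majority Required modal proportion (default 0.60).
#' @return List with \code{pattern} (label or \code{"unassigned"}),
#'   \code{supporting_fraction} and \code{n_snps}.
#' @export
aggregate_gene_pattern <- function(patterns, majority = 0.60) {
  if (length(patterns) == 0L) stop("at least one SNP call required")
  tab <- sort(table(patterns), decreasing = TRUE)
  frac <- tab[1L] / length(patterns)
  list(pattern = if (frac >= majority) names(tab)[1L] else "unassigned",
       supporting_fraction = unname(frac),
       n_snps = length(patterns))
}

#' Full allele-specific regulatory-divergence pipeline
#'
#' Site filtering, per-SNP H/P/T tests, seven-way classification, gene-level
#' majority aggregation and pattern summary, in one call.
#'
#' @param counts Long-format allele-count data frame (see
#'   \code{\link{filter_snps}}).
#' @param genomic_sites Optional DNA-evidence site table passed to the
#'   filter.
#' @param alpha Per-test significance level (default 0.05).
#' @param min_depth,min_het_reads Filter thresholds (defaults 20, 1).
#' @param majority Gene-level modal threshold (default 0.60).
#' @param parent_size_ratio Parent-1 to parent-2 library-size ratio used to
#'   normalize parental counts (default 1, equal libraries).
#' @return List with \code{snp_calls} (one row per SNP: site, p-values,
#'   ratios, pattern), \code{gene_calls} (one row per gene: pattern,
#'   supporting fraction, SNP count, mean ratios for scatter plotting) and
#'   \code{summary} (pattern fractions over assigned-or-not genes).
#' @export
run_ase_pipeline <- function(counts, genomic_sites = NULL, alpha = 0.05,
                             min_depth = 20, min_het_reads = 1,
                             majority = 0.60, parent_size_ratio = 1) {
  filtered <- filter_snps(counts, genomic_sites, min_depth = min_depth,
                          min_het_reads = min_het_reads)
  empty_summary <- data.frame(
    pattern = c(regulatory_patterns, "unassigned"),
    count = 0L, fraction = 0, stringsAsFactors = FALSE)
  if (nrow(filtered) == 0L)
    return(list(snp_calls = NULL, gene_calls = NULL,
                summary = empty_summary,
                filter_log = attr(filtered, "filter_log")))

  key <- paste(filtered$chrom, filtered$pos, filtered$gene_id, sep = ":")
  snp_calls <- do.call(rbind, lapply(split(filtered, key), function(sub) {
    hy <- sub[sub$library == "hybrid", ]
    p1 <- sub[sub$library == "parent1", ]
    p2 <- sub[sub$library == "parent2", ]
    cl <- snp_regulatory_call(hy$allele1_count, hy$allele2_count,
                              p1$allele1_count, p2$allele2_count,
                              alpha = alpha,
                              parent_size_ratio = parent_size_ratio)
    data.frame(chrom = sub$chrom[1L], pos = sub$pos[1L],
               gene_id = sub$gene_id[1L],
               p_P = cl$p_P, p_H = cl$p_H, p_T = cl$p_T,
               log2_ratio_P = cl$log2_ratio_P,
               log2_ratio_H = cl$log2_ratio_H,
               pattern = cl$pattern, stringsAsFactors = FALSE)
  }))
  rownames(snp_calls) <- NULL
  snp_calls <- snp_calls[order(snp_calls$chrom, snp_calls$pos), ]

  gene_calls <- do.call(rbind, lapply(split(snp_calls, snp_calls$gene_id),
                                      function(sub) {
    ag <- aggregate_gene_pattern(sub$pattern, majority = majority)
    data.frame(gene_id = sub$gene_id[1L], pattern = ag$pattern,
               supporting_fraction = ag$supporting_fraction,
               n_snps = ag$n_snps,
               log2_ratio_P = mean(sub$log2_ratio_P),
               log2_ratio_H = mean(sub$log2_ratio_H),
               stringsAsFactors = FALSE)
  }))
  rownames(gene_calls) <- NULL
  gene_calls <- gene_calls[order(gene_calls$gene_id), ]

  lev <- c(regulatory_patterns, "unassigned")
  cnt <- vapply(lev, function(p) sum(gene_calls$pattern == p), integer(1L))
  summary <- data.frame(pattern = lev, count = unname(cnt),
                        fraction = unname(cnt) / nrow(gene_calls),
                        stringsAsFactors = FALSE)
  list(snp_calls = snp_calls, gene_calls = gene_calls, summary = summary,
       filter_log = attr(filtered, "filter_log"))
}
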