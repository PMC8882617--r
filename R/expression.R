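#' Gene-by-sample expression matrix with sample metadata
#'
#' Light container used throughout: a nonnegative numeric matrix of FPKM
#' values (genes in rows) together with per-sample (genotype, stage,
#' replicate) metadata. Sample names follow the
#' \code{<genotype>_<stage>_<replicate>} convention of the TSV interchange
#' format.
#'
#' @param values Numeric matrix, genes x samples, all values >= 0.
#' @param gene_ids Unique gene identifiers, one per row.
#' @param sample_meta Data frame with columns \code{sample}, \code{genotype},
#'   \code{stage}, \code{replicate}, one row per column of \code{values}.
#' @param log2_transformed Logical flag recording whether values are on the
#'   log2(FPKM + 1) scale.
#' @return An object of class \code{"expr_matrix"}.
#' @export
expression_matrix <- function(values, gene_ids, sample_meta,
                              log2_transformed = FALSE) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (length(gene_ids) != nrow(values))
    stop("one gene id per row required")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  need <- c("sample", "genotype", "stage", "replicate")
  if (!all(need %in% names(sample_meta)))
    stop("sample_meta needs columns: ", paste(need, collapse = ", "))
  if (nrow(sample_meta) != ncol(values))
    stop("one metadata row per sample column required")
  rownames(values) <- gene_ids
  colnames(values) <- sample_meta$sample
  structure(list(values = values,
                 meta = as.data.frame(sample_meta,
                                      stringsAsFactors = FALSE),
                 log2_transformed = isTRUE(log2_transformed)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples", if (x$log2_transformed) " [log2(FPKM+1)]", "\n", sep = "")
  cat("Genotypes: ", paste(unique(x$meta$genotype), collapse = ", "),
      "; stages: ", paste(unique(x$meta$stage), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# Column indices of one (genotype, stage) group.
group_columns <- function(matrix, genotype, stage = NULL) {
  sel <- matrix$meta$genotype == genotype
  if (!is.null(stage)) sel <- sel & matrix$meta$stage == stage
  which(sel)
}

#' Transform an expression matrix to log2(FPKM + 1)
#'
#' @param matrix An \code{\link{expression_matrix}} of raw FPKM values.
#' @return The matrix with values replaced by \code{log2(x + 1)} and the
#'   \code{log2_transformed} flag set; metadata is preserved.
#' @export
log_transform <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$log2_transformed)
    warning("matrix is already log2-transformed; transforming again")
  if (any(matrix$values < 0)) stop("negative values cannot be log-transformed")
  matrix$values <- log2(matrix$values + 1)
  matrix$log2_transformed <- TRUE
  matrix
}

#' Pairwise Pearson correlation between replicates of one group
#'
#' Replicate-level QC: the Pearson correlation over all genes for every pair
#' of replicates of one (genotype, stage) group. Zero-variance replicates
#' yield NA with a warning.
#'
#' @param matrix An \code{\link{expression_matrix}}.
#' @param genotype,stage Group selectors.
#' @return Data frame with columns \code{rep_a}, \code{rep_b}, \code{r}.
#' @export
replicate_correlation <- function(matrix, genotype, stage) {
  stopifnot(inherits(matrix, "expr_matrix"))
  cols <- group_columns(matrix, genotype, stage)
  if (length(cols) < 2L)
    stop("group ", genotype, "/", stage, " has fewer than 2 replicates")
  pairs <- utils::combn(cols, 2L)
  res <- data.frame(
    rep_a = matrix$meta$sample[pairs[1L, ]],
    rep_b = matrix$meta$sample[pairs[2L, ]],
    r = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pairs))) {
    a <- matrix$values[, pairs[1L, i]]
    b <- matrix$values[, pairs[2L, i]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("zero-variance replicate in ", genotype, "/", stage,
              "; correlation undefined")
    } else {
      res$r[i] <- stats::cor(a, b)
    }
  }
  res
}

#' Principal component analysis of samples
#'
#' Gene-centered SVD of a log2(FPKM + 1) matrix: each gene is centered
#' across samples (no unit-variance scaling) and samples are projected onto
#' the principal axes.
#'
#' @param matrix An \code{\link{expression_matrix}}, expected on the
#'   log2(FPKM + 1) scale.
#' @param n_components Number of components to return (default 2; capped at
#'   the matrix rank).
#' @return List with \code{scores} (samples x components),
#'   \code{variance_explained} (fraction per returned component) and
#'   \code{rotation} (genes x components).
#' @export
pca_samples <- function(matrix, n_components = 2L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (ncol(matrix$values) < 2L) stop("PCA needs at least 2 samples")
  if (!matrix$log2_transformed)
    warning("input is not flagged log2-transformed; PCA on raw FPKM")
  x <- t(matrix$values - rowMeans(matrix$values))  # samples x genes, centered
  sv <- svd(x)
  keep <- seq_len(min(n_components, sum(sv$d > 1e-10 * sv$d[1L])))
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  dimnames(scores) <- list(colnames(matrix$values),
                           paste0("PC", keep))
  list(scores = scores,
       variance_explained = sv$d[keep]^2 / sum(sv$d^2),
       rotation = structure(sv$v[, keep, drop = FALSE],
                            dimnames = list(rownames(matrix$values),
                                            paste0("PC", keep))))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. Thin validated wrapper around
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Differential expression between two sample groups
#'
#' Per-gene two-sample homoscedastic t-test on log2(FPKM + 1), BH-adjusted,
#' with the three-part filter: larger group mean FPKM > \code{fpkm_min},
#' q < \code{fdr}, and |log2 fold change| > \code{lfc_min}. The fold change
#' is computed on the FPKM scale with a pseudocount,
#' log2((mean_a + eps) / (mean_b + eps)).
#'
#' Externally computed p-values (e.g. from a count-based engine) can be
#' supplied to replace the built-in test; fold changes, means and filtering
#' are then still computed here.
#'
#' @param matrix An \code{\link{expression_matrix}} of raw FPKM values.
#' @param group_a,group_b Lists or vectors \code{c(genotype, stage)}, or a
#'   genotype name when stages are unique.
#' @param fdr,lfc_min,fpkm_min Filter thresholds (defaults 0.05, 1, 1).
#' @param eps Fold-change pseudocount on the FPKM scale (default 0.01).
#' @param p_values Optional externally supplied per-gene p-values, in gene
#'   order.
#' @return Data frame with one row per gene: \code{gene_id},
#'   \code{mean_fpkm_a}, \code{mean_fpkm_b}, \code{log2_fold_change},
#'   \code{p_value}, \code{q_value}, \code{passes}.
#' @export
differential_expression <- function(matrix, group_a, group_b,
                                    fdr = 0.05, lfc_min = 1, fpkm_min = 1,
                                    eps = 0.01, p_values = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$log2_transformed)
    stop("differential_expression expects raw FPKM input")
  resolve <- function(g) {
    g <- as.character(unlist(g))
    cols <- if (length(g) >= 2L) group_columns(matrix, g[1L], g[2L])
            else group_columns(matrix, g[1L])
    if (length(cols) < 2L)
      stop("group ", paste(g, collapse = "/"), " has fewer than 2 replicates")
    cols
  }
  ca <- resolve(group_a); cb <- resolve(group_b)
  va <- matrix$values[, ca, drop = FALSE]
  vb <- matrix$values[, cb, drop = FALSE]
  mean_a <- rowMeans(va); mean_b <- rowMeans(vb)
  lfc <- log2((mean_a + eps) / (mean_b + eps))

  if (is.null(p_values)) {
    la <- log2(va + 1); lb <- log2(vb + 1)
    p_values <- vapply(seq_len(nrow(la)), function(i) {
      a <- la[i, ]; b <- lb[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0)
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }, numeric(1L))
  } else if (length(p_values) != nrow(matrix$values)) {
    stop("external p-values must match the gene count")
  }
  q <- bh_adjust(p_values)
  data.frame(
    gene_id = rownames(matrix$values),
    mean_fpkm_a = mean_a,
    mean_fpkm_b = mean_b,
    log2_fold_change = lfc,
    p_value = p_values,
    q_value = q,
    passes = pmax(mean_a, mean_b) > fpkm_min & q < fdr & abs(lfc) > lfc_min,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test of a gene list against term gene sets
#' drawn from a common universe, BH-adjusted across terms. Generic: any
#' term-to-genes map (GO, pathways, custom sets) can be supplied.
#'
#' @param gene_list Character vector of genes of interest (subset of
#'   \code{universe}).
#' @param term_to_genes Named list mapping term ids to character vectors of
#'   member genes.
#' @param universe Character vector of all assayable genes.
#' @param fdr Significance threshold on q (default 0.05).
#' @return Data frame per term: sizes, overlap, \code{p_value},
#'   \code{q_value}, \code{significant}.
#' @export
term_enrichment <- function(gene_list, term_to_genes, universe, fdr = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    stop("gene_list contains genes outside the universe")
  n_u <- length(universe); n_l <- length(gene_list)
  res <- data.frame(
    term = names(term_to_genes),
    term_size = NA_integer_, overlap = NA_integer_,
    p_value = NA_real_, stringsAsFactors = FALSE
  )
  for (i in seq_along(term_to_genes)) {
    tg <- unique(intersect(term_to_genes[[i]], universe))
    k <- length(intersect(tg, gene_list))
    res$term_size[i] <- length(tg)
    res$overlap[i] <- k
    # P(X >= k) for X ~ Hypergeom(term, universe - term, draws = list size)
    res$p_value[i] <- if (length(tg) == 0L || k == 0L) 1 else
      stats::phyper(k - 1L, length(tg), n_u - length(tg), n_l,
                    lower.tail = FALSE)
  }
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value < fdr
  res
}
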