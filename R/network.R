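#' Keep genes expressed enough for network construction
#'
#' Retains genes with mean FPKM strictly above \code{min_mean} across all
#' samples of the matrix.
#'
#' @param matrix An \code{\link{expression_matrix}}.
#' @param min_mean Mean-FPKM threshold (default 1, strict).
#' @return The filtered matrix; fails if no gene survives.
#' @export
filter_network_genes <- function(matrix, min_mean = 1) {
  stopifnot(inherits(matrix, "expr_matrix"))
  keep <- rowMeans(matrix$values) > min_mean
  if (!any(keep))
    stop("no gene has mean FPKM > ", min_mean, "; nothing to build on")
  matrix$values <- matrix$values[keep, , drop = FALSE]
  matrix
}

#' Soft-thresholded co-expression adjacency
#'
#' Unsigned weighted adjacency a_ij = |cor(i, j)|^beta over samples, unit
#' diagonal. Zero-variance genes have undefined correlations and are
#' dropped with a warning.
#'
#' @param matrix An \code{\link{expression_matrix}} (or a plain genes x
#'   samples numeric matrix).
#' @param beta Positive integer soft-thresholding power.
#' @return Symmetric numeric matrix in [0, 1] with gene ids as dimnames and
#'   attribute \code{"beta"}.
#' @export
compute_adjacency <- function(matrix, beta) {
  vals <- if (inherits(matrix, "expr_matrix")) matrix$values else
    as.matrix(matrix)
  if (ncol(vals) < 3L) stop("at least 3 samples required")
  if (beta < 1 || beta != round(beta)) stop("'beta' must be a positive integer")
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped from the network")
    vals <- vals[sds > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(vals)))^beta
  diag(a) <- 1
  a <- (a + t(a)) / 2   # enforce exact symmetry against rounding
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' connectivity k_i = sum_{j != i} a_ij and the inner sum over u != i, j;
#' diagonal set to 1. High overlap means two genes share network neighbours
#' beyond their direct link.
#'
#' @param adj Adjacency matrix from \code{\link{compute_adjacency}}.
#' @return Symmetric matrix in [0, 1], unit diagonal, same dimnames.
#' @export
compute_tom <- function(adj) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj) || max(abs(adj - t(adj))) > 1e-12)
    stop("adjacency must be a symmetric square matrix")
  if (any(adj < 0 | adj > 1)) stop("adjacency entries must lie in [0, 1]")
  if (any(diag(adj) != 1)) stop("adjacency diagonal must be exactly 1")
  k <- rowSums(adj) - 1
  # numerator sum_{u != i,j} a_iu a_uj + a_ij: (A^2)_ij counts u = i and
  # u = j, each contributing a_ij (unit diagonal), so subtract 2 a_ij.
  num <- adj %*% adj - 2 * adj + adj
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - adj)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Module eigengene
#'
#' First principal component of a module's standardized expression: each
#' gene is scaled to mean 0, sd 1 across samples, and the unit-norm first
#' right singular vector over samples is returned, with its sign fixed so
#' the eigengene correlates nonnegatively with the module's mean
#' standardized expression.
#'
#' @param matrix An \code{\link{expression_matrix}} or plain genes x samples
#'   matrix.
#' @param module_genes Gene ids (row names) of the module.
#' @return List with \code{scores} (named per-sample vector, unit norm) and
#'   \code{variance_explained} (first singular value's share of total
#'   variance).
#' @export
compute_eigengene <- function(matrix, module_genes) {
  vals <- if (inherits(matrix, "expr_matrix")) matrix$values else
    as.matrix(matrix)
  if (length(module_genes) == 0L) stop("module is empty")
  missing <- setdiff(module_genes, rownames(vals))
  if (length(missing) > 0L)
    stop("unknown module genes: ", paste(missing, collapse = ", "))
  x <- vals[module_genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped from the eigengene")
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) == 0L) stop("no variable gene left in the module")
  }
  x <- t(scale(t(x)))
  sv <- svd(x)
  scores <- sv$v[, 1L]
  mean_expr <- colMeans(x)
  if (stats::sd(mean_expr) > 0 && stats::cor(scores, mean_expr) < 0)
    scores <- -scores
  names(scores) <- colnames(vals)
  list(scores = scores, variance_explained = sv$d[1L]^2 / sum(sv$d^2))
}

# Eigengene score matrix (samples x modules) for a module assignment.
eigengene_matrix <- function(vals, assignment) {
  mods <- setdiff(unique(assignment$module), "unassigned")
  scores <- vapply(mods, function(m) {
    compute_eigengene(vals, assignment$gene_id[assignment$module == m])$scores
  }, numeric(ncol(vals)))
  colnames(scores) <- mods
  scores
}

#' Detect co-expression modules by TOM clustering with eigengene merging
#'
#' Average-linkage hierarchical clustering on 1 - TOM, cut at the merge
#' height that yields the most clusters of at least \code{min_size} genes
#' (ties resolved toward the higher, coarser height); clusters below
#' \code{min_size} are dissolved to unassigned. Modules whose eigengene
#' dissimilarity 1 - cor falls below \code{merge_cut} are then merged
#' iteratively, closest pair first, recomputing eigengenes after every
#' merge, until all pairs are separated by at least \code{merge_cut}.
#'
#' @param matrix A filtered \code{\link{expression_matrix}}.
#' @param beta Soft-thresholding power.
#' @param min_size Minimum module size (default 50).
#' @param merge_cut Eigengene-dissimilarity merge threshold (default 0.15).
#' @return List with \code{assignment} (data frame gene_id, module; modules
#'   labelled \code{"M1"}, \code{"M2"}, ... by decreasing size),
#'   \code{eigengenes} (samples x modules score matrix),
#'   \code{variance_explained} (per module), \code{tom}, \code{adjacency},
#'   \code{cut_height} and \code{n_merged} (merge steps taken).
#' @export
detect_modules <- function(matrix, beta, min_size = 50, merge_cut = 0.15) {
  stopifnot(inherits(matrix, "expr_matrix"))
  vals <- matrix$values
  if (nrow(vals) < min_size) {
    warning("fewer than ", min_size, " genes; no module can form")
    return(list(assignment = data.frame(gene_id = rownames(vals),
                                        module = "unassigned",
                                        stringsAsFactors = FALSE),
                eigengenes = NULL, variance_explained = NULL,
                tom = NULL, adjacency = NULL, cut_height = NA_real_,
                n_merged = 0L))
  }
  adj <- compute_adjacency(matrix, beta)
  tom <- compute_tom(adj)
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")

  heights <- sort(unique(tree$height))
  best_h <- NA_real_; best_score <- -1L
  for (h in heights) {
    cl <- stats::cutree(tree, h = h)
    score <- sum(table(cl) >= min_size)
    if (score >= best_score) { best_score <- score; best_h <- h }
  }
  cl <- stats::cutree(tree, h = best_h)
  sizes <- table(cl)
  module <- ifelse(sizes[as.character(cl)] >= min_size,
                   paste0("C", cl), "unassigned")
  assignment <- data.frame(gene_id = rownames(tom), module = module,
                           stringsAsFactors = FALSE)

  # iterative eigengene merging
  n_merged <- 0L
  repeat {
    mods <- setdiff(unique(assignment$module), "unassigned")
    if (length(mods) < 2L) break
    me <- eigengene_matrix(vals, assignment)
    diss <- 1 - stats::cor(me)
    diag(diss) <- Inf
    if (min(diss) >= merge_cut) break
    pair <- which(diss == min(diss), arr.ind = TRUE)[1L, ]
    from <- colnames(diss)[max(pair)]; into <- colnames(diss)[min(pair)]
    assignment$module[assignment$module == from] <- into
    n_merged <- n_merged + 1L
  }

  # relabel by decreasing size
  mods <- setdiff(unique(assignment$module), "unassigned")
  if (length(mods) > 0L) {
    sizes <- vapply(mods, function(m) sum(assignment$module == m), integer(1L))
    relabel <- stats::setNames(paste0("M", seq_along(mods)),
                               mods[order(-sizes, mods)])
    assignment$module <- ifelse(assignment$module == "unassigned",
                                "unassigned", relabel[assignment$module])
    me <- eigengene_matrix(vals, assignment)
    ve <- vapply(colnames(me), function(m) {
      compute_eigengene(vals,
                        assignment$gene_id[assignment$module == m]
                        )$variance_explained
    }, numeric(1L))
  } else {
    me <- NULL; ve <- NULL
  }
  list(assignment = assignment, eigengenes = me, variance_explained = ve,
       tom = tom, adjacency = adj, cut_height = best_h, n_merged = n_merged)
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation and two-tailed p-value for every (module, trait)
#' pair; a pair is flagged significant at p < \code{alpha}. Missing trait
#' values are handled pairwise-complete and the effective n is reported.
#'
#' @param eigengenes Samples x modules score matrix (from
#'   \code{\link{detect_modules}}).
#' @param traits Samples x traits data frame, rows aligned with the
#'   eigengene rows.
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with columns \code{module}, \code{trait}, \code{r},
#'   \code{p_value}, \code{n}, \code{significant}.
#' @export
module_trait_correlation <- function(eigengenes, traits, alpha = 0.05) {
  eigengenes <- as.matrix(eigengenes)
  if (nrow(eigengenes) != nrow(traits))
    stop("eigengene and trait tables must cover the same samples")
  out <- expand.grid(module = colnames(eigengenes), trait = names(traits),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p_value <- NA_real_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    x <- eigengenes[, out$module[i]]
    y <- traits[[out$trait[i]]]
    ok <- stats::complete.cases(x, y)
    out$n[i] <- sum(ok)
    if (sum(ok) >= 3L && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok])
      out$r[i] <- unname(ct$estimate)
      out$p_value[i] <- ct$p.value
    }
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Extract hub genes by intramodular connectivity
#'
#' Ranks the genes of each module by intramodular connectivity
#' k_i = sum_{j in module, j != i} a_ij, the sum of the gene's soft
#' adjacency to the other module members, and keeps the top \code{top_n}.
#' Whole-network connectivity is reported alongside. Set
#' \code{soft = FALSE} to rank by raw |correlation| sums instead of
#' soft-thresholded adjacency.
#'
#' @param matrix The \code{\link{expression_matrix}} the network was built
#'   from.
#' @param assignment Module assignment data frame (gene_id, module).
#' @param beta Soft power used for the adjacency.
#' @param top_n Hub count per module (default 30); smaller modules are
#'   returned whole.
#' @param soft Use |cor|^beta (default) or |cor| for connectivity.
#' @return Data frame with columns \code{module}, \code{gene_id}, \code{k}
#'   (intramodular), \code{k_total} (whole network), \code{rank}; k is
#'   nonincreasing within each module, ties broken by gene id.
#' @export
extract_hubs <- function(matrix, assignment, beta, top_n = 30, soft = TRUE) {
  adj <- compute_adjacency(matrix, if (soft) beta else 1L)
  k_total <- rowSums(adj) - 1
  mods <- setdiff(unique(assignment$module), "unassigned")
  out <- lapply(sort(mods), function(m) {
    genes <- intersect(assignment$gene_id[assignment$module == m],
                       rownames(adj))
    sub <- adj[genes, genes, drop = FALSE]
    k <- rowSums(sub) - 1
    ord <- order(-k, genes)
    keep <- ord[seq_len(min(top_n, length(genes)))]
    data.frame(module = m, gene_id = genes[keep], k = unname(k[keep]),
               k_total = unname(k_total[genes[keep]]),
               rank = seq_along(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Export the network as a thresholded edge list
#'
#' Undirected edges with TOM weight at or above the threshold, one record
#' per gene pair (first id < second id in matrix order), ordered by
#' decreasing weight then lexicographically — ready for graph viewers.
#'
#' @param tom Topological overlap matrix.
#' @param assignment Optional module assignment; when given, each endpoint's
#'   module is annotated and unassigned-unassigned edges are kept too.
#' @param weight_threshold Minimum edge weight (default 0.20).
#' @return Data frame with columns \code{source}, \code{target},
#'   \code{weight} (plus module columns when an assignment is supplied).
#' @export
export_network <- function(tom, assignment = NULL, weight_threshold = 0.20) {
  tom <- as.matrix(tom)
  ut <- upper.tri(tom)
  idx <- which(ut & tom >= weight_threshold, arr.ind = TRUE)
  edges <- data.frame(
    source = rownames(tom)[idx[, 1L]],
    target = colnames(tom)[idx[, 2L]],
    weight = tom[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$weight, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(assignment)) {
    mod <- stats::setNames(assignment$module, assignment$gene_id)
    edges$source_module <- unname(mod[edges$source])
    edges$target_module <- unname(mod[edges$target])
  }
  edges
}
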