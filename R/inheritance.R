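#' Classify the inheritance mode of one gene's hybrid expression
#'
#' Tests F1 replicate expression against per-replicate mid-parent values
#' (MPV, the replicate-wise average of the two parents) with a two-tailed
#' homoscedastic t-test. Genes not rejected at \code{alpha} are additive;
#' rejected genes are subdivided by the F1 mean m: above both parent means
#' is over-dominance, below both is under-dominance, otherwise (the closed
#' parental interval) dominance.
#'
#' @param f1_reps,p1_reps,p2_reps Numeric replicate vectors (>= 2 values
#'   each; the parents must have equal length so MPVs pair up).
#' @param alpha Significance level for the F1-vs-MPV test (default 0.05).
#' @return List with \code{p_value}, \code{mode}, \code{f1_mean},
#'   \code{mpv_mean}.
#' @export
classify_inheritance <- function(f1_reps, p1_reps, p2_reps, alpha = 0.05) {
  if (length(f1_reps) < 2L || length(p1_reps) < 2L || length(p2_reps) < 2L)
    stop("each group needs at least 2 replicates")
  if (length(p1_reps) != length(p2_reps))
    stop("parent replicate vectors must have equal length to form MPVs")
  if (any(c(f1_reps, p1_reps, p2_reps) < 0))
    stop("expression values must be nonnegative")
  mpv <- (p1_reps + p2_reps) / 2
  if (stats::sd(f1_reps) == 0 && stats::sd(mpv) == 0) {
    if (isTRUE(all.equal(mean(f1_reps), mean(mpv)))) {
      p <- 1
    } else {
      warning("zero pooled variance with unequal means; p set to 0")
      p <- 0
    }
  } else {
    p <- stats::t.test(f1_reps, mpv, var.equal = TRUE)$p.value
  }
  m <- mean(f1_reps)
  mode <- if (p >= alpha) "additive"
          else if (m > max(mean(p1_reps), mean(p2_reps))) "over-dominance"
          else if (m < min(mean(p1_reps), mean(p2_reps))) "under-dominance"
          else "dominance"
  list(p_value = p, mode = mode, f1_mean = m, mpv_mean = mean(mpv))
}

#' Classify inheritance modes for all genes of an F1/P1/P2 trio
#'
#' Applies \code{\link{classify_inheritance}} gene-wise to an expression
#' matrix holding the hybrid and both parents at one stage. Typically run on
#' genes already flagged as differentially expressed in the relevant
#' hybrid-parent comparisons; the function itself accepts any gene set.
#'
#' @param matrix An \code{\link{expression_matrix}} of raw FPKM values.
#' @param f1,p1,p2 Genotype names of the hybrid and parents.
#' @param stage Stage label selecting the samples (default: the single stage
#'   present).
#' @param genes Optional gene-id subset (e.g. DEGs).
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns \code{gene_id}, \code{p_value},
#'   \code{mode}.
#' @export
classify_trio <- function(matrix, f1, p1, p2, stage = NULL, genes = NULL,
                          alpha = 0.05) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (is.null(stage)) {
    stage <- unique(matrix$meta$stage)
    if (length(stage) != 1L) stop("multiple stages present; specify 'stage'")
  }
  cf1 <- group_columns(matrix, f1, stage)
  cp1 <- group_columns(matrix, p1, stage)
  cp2 <- group_columns(matrix, p2, stage)
  if (length(cp1) != length(cp2))
    stop("parents must have equal replicate counts to form MPVs")
  vals <- matrix$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(vals))
    if (length(missing) > 0L)
      stop("unknown genes: ", paste(missing, collapse = ", "))
    vals <- vals[genes, , drop = FALSE]
  }
  out <- data.frame(gene_id = rownames(vals), p_value = NA_real_,
                    mode = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(vals))) {
    cl <- classify_inheritance(vals[i, cf1], vals[i, cp1], vals[i, cp2],
                               alpha = alpha)
    out$p_value[i] <- cl$p_value
    out$mode[i] <- cl$mode
  }
  out
}

#' Summarize inheritance-mode calls
#'
#' @param calls Data frame with a \code{mode} column (from
#'   \code{\link{classify_trio}}).
#' @return Data frame with one row per mode: \code{mode}, \code{count},
#'   \code{fraction}. All four modes are always listed; fractions sum to 1.
#' @export
summarize_modes <- function(calls) {
  if (nrow(calls) == 0L) stop("empty call collection")
  modes <- c("additive", "dominance", "over-dominance", "under-dominance")
  counts <- vapply(modes, function(m) sum(calls$mode == m), integer(1L))
  data.frame(mode = modes, count = unname(counts),
             fraction = unname(counts) / nrow(calls),
             stringsAsFactors = FALSE)
}
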