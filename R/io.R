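#' Read an expression TSV
#'
#' Expected layout: first column \code{gene_id}, remaining columns named
#' \code{<genotype>_<stage>_<replicate>}. The header is parsed from the
#' right, so genotype names may not contain underscores but are otherwise
#' free.
#'
#' @param path TSV file path.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id")
    stop("first column must be 'gene_id', found '", names(df)[1L], "'")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  samples <- names(df)[-1L]
  parts <- strsplit(samples, "_")
  bad <- samples[lengths(parts) < 3L]
  if (length(bad) > 0L)
    stop("malformed sample column(s), expected <genotype>_<stage>_<rep>: ",
         paste(bad, collapse = ", "))
  meta <- data.frame(
    sample = samples,
    genotype = vapply(parts, function(p)
      paste(p[seq_len(length(p) - 2L)], collapse = "_"), character(1L)),
    stage = vapply(parts, function(p) p[length(p) - 1L], character(1L)),
    replicate = as.integer(vapply(parts, function(p) p[length(p)],
                                  character(1L))),
    stringsAsFactors = FALSE
  )
  vals <- as.matrix(df[-1L])
  if (!is.numeric(vals)) stop("non-numeric expression cell(s) in ", path)
  expression_matrix(vals, gene_ids = df$gene_id, sample_meta = meta)
}

#' Write an expression matrix as TSV
#'
#' @param matrix An \code{\link{expression_matrix}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  df <- data.frame(gene_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait table TSV
#'
#' First column \code{sample}, remaining columns numeric trait values
#' (FKW, DKW, TKL, TKW in the kernel application).
#'
#' @param path TSV file path.
#' @return Data frame with sample row names.
#' @export
read_traits_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample") stop("first column must be 'sample'")
  rownames(df) <- df$sample
  df[-1L]
}

#' Read biallelic SNP sites from a VCF
#'
#' Loads the fixed columns of a VCF and returns the biallelic sites as a
#' (chrom, pos, ref, alt) table; POS stays 1-based throughout.
#' Multiallelic records (comma in ALT) are skipped and counted.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return Data frame with columns \code{chrom}, \code{pos} (integer,
#'   1-based), \code{ref}, \code{alt}; attribute \code{"n_multiallelic"}
#'   holds the skipped-record count.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    message(sum(multi), " multiallelic record(s) skipped")
  fix <- fix[!multi, , drop = FALSE]
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  attr(out, "n_multiallelic") <- sum(multi)
  out
}

#' Write the long-format allele-count table as TSV
#'
#' @param counts Allele-count data frame (see \code{\link{filter_snps}}).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_allele_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read the long-format allele-count table
#'
#' @param path TSV path written by \code{\link{write_allele_counts_tsv}}.
#' @return Allele-count data frame.
#' @export
read_allele_counts_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# 64-bit FNV-1a over a string, reported as 16 hex digits; used to stamp
# outputs with a config fingerprint without extra dependencies.
fnv1a_hash <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "")))
  lo <- 0x84222325; hi <- 0xcbf29ce4   # FNV offset basis, split 32/32
  m <- 2^32
  for (b in bytes) {
    # xor touches only the low byte (b < 256); avoids 32-bit overflow
    lo <- (lo %/% 256) * 256 + bitwXor(lo %% 256, b)
    # multiply (hi,lo) by the FNV prime 0x100000001b3 mod 2^64
    new_lo <- (lo * 0x1b3) %% m
    carry <- floor(lo * 0x1b3 / m)
    new_hi <- (hi * 0x1b3 + lo + carry) %% m
    lo <- new_lo; hi <- new_hi
  }
  to_hex <- function(x) {
    d <- integer(8L)
    for (i in 8:1) { d[i] <- x %% 16; x <- x %/% 16 }
    paste(strsplit("0123456789abcdef", "")[[1L]][d + 1L], collapse = "")
  }
  paste0(to_hex(hi), to_hex(lo))
}

#' Default end-to-end run configuration
#'
#' Collects every analysis threshold (at its field default) and the
#' synthetic-run sizes into one list consumed by \code{\link{run_all}}.
#'
#' @param seed Integer seed driving all simulation.
#' @param beta Soft power for the network stage (default 9; 6 is the
#'   conventional choice for the earliest developmental stage).
#' @return Named list of class \code{"run_config"}.
#' @export
default_run_config <- function(seed = 1L, beta = 9L) {
  structure(list(
    seed = as.integer(seed),
    alpha = 0.05, fdr = 0.05, lfc_min = 1, fpkm_min = 1,
    min_depth = 20, majority = 0.60,
    beta = as.integer(beta), min_size = 50L, merge_cut = 0.15,
    edge_threshold = 0.20, top_n = 30L,
    genes_per_category = 50L, read_depth_per_snp = 200,
    n_modules = 5L, genes_per_module = 60L, n_background_genes = 100L,
    factor_loading = 0.9, hubs_per_module = 0L,
    noise_sd = 0.1, trait_noise_sd = 0.1,
    expression_file = NULL, counts_file = NULL, traits_file = NULL,
    vcf_file = NULL
  ), class = "run_config")
}

#' Run the full analysis stack
#'
#' Executes the three analysis arms — trio differential expression and
#' inheritance-mode classification, allele-specific regulatory-divergence
#' assignment, and co-expression module/trait/hub analysis — writing every
#' stage's table plus a JSON summary stamped with the seed and a config
#' fingerprint. Inputs are simulated with planted truth unless file inputs
#' are set in the config; a configured-but-missing traits file skips the
#' network stage with a warning.
#'
#' @param config A \code{\link{default_run_config}} list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the summary (as written) and the paths of
#'   all emitted files.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  summary <- list(seed = config$seed,
                  config_hash = fnv1a_hash(jsonlite::toJSON(
                    config[!vapply(config, is.null, logical(1L))],
                    auto_unbox = TRUE, digits = NA)))

  # --- trio arm: DEGs, then inheritance modes on the DEGs -----------------
  sim_cfg <- simulation_config(
    seed = config$seed, genes_per_category = config$genes_per_category,
    read_depth_per_snp = config$read_depth_per_snp,
    n_modules = config$n_modules, genes_per_module = config$genes_per_module,
    n_background_genes = config$n_background_genes,
    factor_loading = config$factor_loading,
    hubs_per_module = config$hubs_per_module,
    noise_sd = config$noise_sd, trait_noise_sd = config$trait_noise_sd)
  trio <- if (is.null(config$expression_file)) {
    simulate_trio_expression(sim_cfg)
  } else {
    list(expression = read_expression_tsv(config$expression_file),
         truth = NULL)
  }
  expr <- trio$expression
  write_expression_tsv(expr, file.path(out_dir, "expression.tsv"))
  paths[["expression.tsv"]] <- file.path(out_dir, "expression.tsv")

  geno <- unique(expr$meta$genotype)
  if (!all(c("F1", "P1", "P2") %in% geno))
    stop("trio stage expects genotypes F1, P1, P2 in the expression matrix")
  stage <- unique(expr$meta$stage)[1L]
  deg1 <- differential_expression(expr, c("F1", stage), c("P1", stage),
                                  fdr = config$fdr, lfc_min = config$lfc_min,
                                  fpkm_min = config$fpkm_min)
  deg2 <- differential_expression(expr, c("F1", stage), c("P2", stage),
                                  fdr = config$fdr, lfc_min = config$lfc_min,
                                  fpkm_min = config$fpkm_min)
  emit(deg1, "deg_f1_vs_p1.tsv"); emit(deg2, "deg_f1_vs_p2.tsv")
  degs <- union(deg1$gene_id[deg1$passes], deg2$gene_id[deg2$passes])
  if (length(degs) == 0L) degs <- deg1$gene_id   # degenerate input fallback
  modes <- classify_trio(expr, "F1", "P1", "P2", stage = stage,
                         genes = degs, alpha = config$alpha)
  emit(modes, "inheritance_modes.tsv")
  mode_summary <- summarize_modes(modes)
  summary$n_degs <- length(degs)
  summary$mode_fractions <- stats::setNames(as.list(mode_summary$fraction),
                                            mode_summary$mode)

  # --- ASE arm ------------------------------------------------------------
  ase_in <- if (is.null(config$counts_file)) {
    simulate_regulatory_counts(sim_cfg)
  } else {
    list(counts = read_allele_counts_tsv(config$counts_file), truth = NULL)
  }
  genomic <- if (!is.null(config$vcf_file)) read_variants_vcf(config$vcf_file)
             else NULL
  write_allele_counts_tsv(ase_in$counts,
                          file.path(out_dir, "allele_counts.tsv"))
  paths[["allele_counts.tsv"]] <- file.path(out_dir, "allele_counts.tsv")
  ase <- run_ase_pipeline(ase_in$counts, genomic, alpha = config$alpha,
                          min_depth = config$min_depth,
                          majority = config$majority)
  if (!is.null(ase$snp_calls)) emit(ase$snp_calls, "snp_regulatory_calls.tsv")
  if (!is.null(ase$gene_calls))
    emit(ase$gene_calls, "gene_regulatory_calls.tsv")
  summary$pattern_fractions <- stats::setNames(as.list(ase$summary$fraction),
                                               ase$summary$pattern)
  summary$ase_filter_log <- as.list(ase$filter_log)

  # --- network arm --------------------------------------------------------
  skip_network <- FALSE
  if (!is.null(config$traits_file) && !file.exists(config$traits_file)) {
    warning("traits file '", config$traits_file,
            "' not found; network stage skipped")
    skip_network <- TRUE
  }
  if (!skip_network) {
    mod_sim <- simulate_module_expression(sim_cfg)
    traits <- if (!is.null(config$traits_file))
      read_traits_tsv(config$traits_file) else mod_sim$traits
    net_expr <- filter_network_genes(mod_sim$expression,
                                     min_mean = config$fpkm_min)
    det <- detect_modules(net_expr, beta = config$beta,
                          min_size = config$min_size,
                          merge_cut = config$merge_cut)
    emit(det$assignment, "module_assignment.tsv")
    if (!is.null(det$eigengenes)) {
      mt <- module_trait_correlation(det$eigengenes, traits,
                                     alpha = config$alpha)
      emit(mt, "module_trait.tsv")
      hubs <- extract_hubs(net_expr, det$assignment, beta = config$beta,
                           top_n = config$top_n)
      emit(hubs, "hub_genes.tsv")
      edges <- export_network(det$tom, det$assignment,
                              weight_threshold = config$edge_threshold)
      emit(edges, "network_edges.tsv")
      summary$n_modules <- ncol(det$eigengenes)
      summary$module_trait <- mt
      summary$n_edges <- nrow(edges)
    } else {
      summary$n_modules <- 0L
    }
  }

  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  paths[["summary.json"]] <- sp
  invisible(list(summary = summary, paths = paths))
}
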