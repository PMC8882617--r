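#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator into a validated list.
#' The defaults are the study conditions the downstream recovery tests assume:
#' three biological replicates, strong regulatory effects of 2 log2 units,
#' sequencing depth of 200 reads per SNP, and 24-sample module matrices.
#'
#' @param seed Integer seed; fixing it makes every generator byte-reproducible.
#' @param n_replicates Biological replicates per genotype (default 3).
#' @param genes_per_category Genes simulated per regulatory category or
#'   inheritance mode (default 100).
#' @param read_depth_per_snp Mean total read depth per SNP per replicate
#'   library (default 200).
#' @param nb_dispersion Negative-binomial dispersion of the per-replicate
#'   depth, method-of-moments parameterization: variance = mu + dispersion *
#'   mu^2. The default 0 gives Poisson depth, under which the pooled
#'   chi-square tests downstream hold their nominal level; positive values
#'   add overdispersion at the cost of anticonservative parental-ratio
#'   tests.
#' @param cis_effect Magnitude of the cis effect c in log2 units (default 2).
#' @param trans_effect Magnitude of the trans effect t in log2 units
#'   (default 2).
#' @param snps_per_gene SNP sites simulated per gene (default 1).
#' @param n_modules Latent co-expression modules (default 5).
#' @param genes_per_module Genes per planted module (default 60).
#' @param n_background_genes Pure-noise genes added to module matrices
#'   (default 100).
#' @param n_samples Samples in module matrices (default 24).
#' @param factor_loading Loading of module genes on their latent factor, in
#'   [0,1] (default 0.9). Expected within-module gene-gene correlation is
#'   the square of this value.
#' @param hubs_per_module Genes per module planted at \code{hub_loading}
#'   instead of \code{factor_loading} (default 0).
#' @param hub_loading Loading for planted hub genes (default 0.98).
#' @param noise_sd Lognormal noise sd, in log2 units, for trio FPKM
#'   replicates (default 0.1).
#' @param trait_noise_sd Gaussian noise sd added to the module factor when a
#'   trait is generated from it (default 0.1).
#' @param delta Over/under-dominance offset in log2 units: over-dominant F1
#'   means are mu2 * 2^delta, under-dominant mu1 * 2^-delta (default 1).
#'
#' @return A list of class \code{"sim_config"}.
#' @export
simulation_config <- function(seed = 1L,
                              n_replicates = 3L,
                              genes_per_category = 100L,
                              read_depth_per_snp = 200,
                              nb_dispersion = 0,
                              cis_effect = 2,
                              trans_effect = 2,
                              snps_per_gene = 1L,
                              n_modules = 5L,
                              genes_per_module = 60L,
                              n_background_genes = 100L,
                              n_samples = 24L,
                              factor_loading = 0.9,
                              hubs_per_module = 0L,
                              hub_loading = 0.98,
                              noise_sd = 0.1,
                              trait_noise_sd = 0.1,
                              delta = 1) {
  cfg <- list(seed = as.integer(seed),
              n_replicates = as.integer(n_replicates),
              genes_per_category = as.integer(genes_per_category),
              read_depth_per_snp = read_depth_per_snp,
              nb_dispersion = nb_dispersion,
              cis_effect = cis_effect,
              trans_effect = trans_effect,
              snps_per_gene = as.integer(snps_per_gene),
              n_modules = as.integer(n_modules),
              genes_per_module = as.integer(genes_per_module),
              n_background_genes = as.integer(n_background_genes),
              n_samples = as.integer(n_samples),
              factor_loading = factor_loading,
              hubs_per_module = as.integer(hubs_per_module),
              hub_loading = hub_loading,
              noise_sd = noise_sd,
              trait_noise_sd = trait_noise_sd,
              delta = delta)
  counts <- c("n_replicates", "genes_per_category", "snps_per_gene",
              "n_modules", "genes_per_module", "n_samples")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop("'", f, "' must be >= 1")
  }
  if (cfg$n_background_genes < 0L) stop("'n_background_genes' must be >= 0")
  if (cfg$read_depth_per_snp <= 0) stop("'read_depth_per_snp' must be positive")
  if (cfg$nb_dispersion < 0) stop("'nb_dispersion' must be nonnegative")
  if (cfg$factor_loading < 0 || cfg$factor_loading > 1)
    stop("'factor_loading' must lie in [0, 1]")
  if (cfg$hub_loading < 0 || cfg$hub_loading > 1)
    stop("'hub_loading' must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$trait_noise_sd < 0)
    stop("noise standard deviations must be nonnegative")
  if (cfg$delta <= 0) stop("'delta' must be positive for over/under-dominance")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  for (f in setdiff(names(x), "seed"))
    cat("  ", f, ": ", format(x[[f]]), "\n", sep = "")
  invisible(x)
}

# Depth draw: NB by method of moments (var = mu + disp*mu^2); Poisson at
# disp = 0. Returns integers >= 0.
rdepth <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

# Per-category (c, t) effect map. With |c| = |t| and opposite signs the pair
# is compensatory by definition, so cis x trans uses t = -2c to keep the
# signs opposite while c != -t.
regulatory_effect_map <- function(c0, t0) {
  data.frame(
    category = c("cis-only", "trans-only", "cis+trans", "cis×trans",
                 "compensatory", "conserved"),
    c = c(c0, 0, c0, c0, c0, 0),
    t = c(0, t0, t0, -2 * t0, -c0, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulate allele-specific SNP counts under cis/trans regulatory divergence
#'
#' Generates per-SNP, per-replicate allele counts for a hybrid and its two
#' homozygous parents under the six regulatory-divergence categories, with
#' planted ground truth. The hybrid allele-1 fraction is 2^c / (1 + 2^c)
#' (cis effects survive in the shared trans environment of the hybrid),
#' while the two parental libraries have mean depths differing by the factor
#' 2^(c+t) (parents express cis and trans divergence jointly).
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list with \code{counts}, a data frame in the long allele-count
#'   layout (chrom, pos, gene_id, library, replicate, allele1_count,
#'   allele2_count), and \code{truth}, a ground-truth data frame with one
#'   row per gene.
#' @export
simulate_regulatory_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  eff <- regulatory_effect_map(config$cis_effect, config$trans_effect)
  nrep <- config$n_replicates
  npg <- config$genes_per_category
  nsnp <- config$snps_per_gene
  depth <- config$read_depth_per_snp
  disp <- config$nb_dispersion

  rows <- vector("list", nrow(eff) * npg)
  truth <- vector("list", nrow(eff) * npg)
  idx <- 0L
  pos_counter <- 0L
  for (k in seq_len(nrow(eff))) {
    cc <- eff$c[k]; tt <- eff$t[k]
    p_hyb <- 2^cc / (1 + 2^cc)
    # parental library means, symmetric about the nominal depth
    mu_p1 <- depth * 2^((cc + tt) / 2)
    mu_p2 <- depth * 2^(-(cc + tt) / 2)
    for (g in seq_len(npg)) {
      idx <- idx + 1L
      safe <- c("cis-only" = "cisonly", "trans-only" = "transonly",
                "cis+trans" = "cisplustrans", "cis×trans" = "cisxtrans",
                "compensatory" = "compensatory", "conserved" = "conserved")
      gid <- sprintf("gene_%s_%03d", safe[[eff$category[k]]], g)
      snp_rows <- vector("list", nsnp)
      for (s in seq_len(nsnp)) {
        pos_counter <- pos_counter + 10L
        hyb_depth <- rdepth(nrep, depth, disp)
        hyb_a1 <- stats::rbinom(nrep, hyb_depth, p_hyb)
        p1_cnt <- rdepth(nrep, mu_p1, disp)
        p2_cnt <- rdepth(nrep, mu_p2, disp)
        snp_rows[[s]] <- data.frame(
          chrom = "chr1",
          pos = pos_counter,
          gene_id = gid,
          library = rep(c("hybrid", "parent1", "parent2"), each = nrep),
          replicate = rep(seq_len(nrep), 3L),
          allele1_count = c(hyb_a1, p1_cnt, integer(nrep)),
          allele2_count = c(hyb_depth - hyb_a1, integer(nrep), p2_cnt),
          stringsAsFactors = FALSE
        )
      }
      rows[[idx]] <- do.call(rbind, snp_rows)
      truth[[idx]] <- data.frame(gene_id = gid,
                                 regulatory_category = eff$category[k],
                                 c = cc, t = tt,
                                 stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(counts = counts, truth = do.call(rbind, truth))
}

#' Simulate F1/parent trio expression under the four inheritance modes
#'
#' Draws per-gene parental means mu1 < mu2 and plants the F1 mean according
#' to the mode: additive at the mid-parent value, dominance strictly between
#' mid-parent and the high parent (at (mu1 + 3*mu2)/4), over-dominance at
#' mu2 * 2^delta and under-dominance at mu1 * 2^-delta. Replicates are the
#' mode mean times lognormal noise with sd \code{noise_sd} log2 units.
#'
#' Dominance is planted strictly inside the parental interval rather than at
#' the high parent itself: a gene sitting exactly on the higher parent is on
#' the dominance/over-dominance decision boundary and cannot be recovered
#' better than a coin flip by any mean-comparison rule.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param modes Character vector of modes to simulate (default all four).
#' @return A list with \code{expression}, an expression matrix object (see
#'   \code{\link{expression_matrix}}) with genotypes F1, P1, P2, and
#'   \code{truth}, a per-gene data frame with the planted mode and means.
#' @export
simulate_trio_expression <- function(config,
                                     modes = c("additive", "dominance",
                                               "over-dominance",
                                               "under-dominance")) {
  stopifnot(inherits(config, "sim_config"))
  modes <- match.arg(modes, several.ok = TRUE)
  set.seed(config$seed + 1L)
  npg <- config$genes_per_category
  nrep <- config$n_replicates
  n <- npg * length(modes)

  mu1 <- stats::runif(n, 2, 10)
  mu2 <- mu1 * 2^stats::runif(n, 1.5, 2.5)   # 1.5-2.5 log2 units apart
  mode <- rep(modes, each = npg)
  f1_mean <- ifelse(mode == "additive", (mu1 + mu2) / 2,
             ifelse(mode == "dominance", (mu1 + 3 * mu2) / 4,
             ifelse(mode == "over-dominance", mu2 * 2^config$delta,
                    mu1 * 2^(-config$delta))))

  gid <- sprintf("gene_%s_%03d", gsub("-", "", mode),
                 sequence(rep(npg, length(modes))))
  noise <- function(m) m * 2^stats::rnorm(length(m), 0, config$noise_sd)
  vals <- matrix(0, nrow = n, ncol = 3L * nrep)
  for (r in seq_len(nrep)) {
    vals[, r] <- noise(f1_mean)
    vals[, nrep + r] <- noise(mu1)
    vals[, 2L * nrep + r] <- noise(mu2)
  }
  meta <- data.frame(
    sample = paste0(rep(c("F1", "P1", "P2"), each = nrep), "_S1_",
                    rep(seq_len(nrep), 3L)),
    genotype = rep(c("F1", "P1", "P2"), each = nrep),
    stage = "S1",
    replicate = rep(seq_len(nrep), 3L),
    stringsAsFactors = FALSE
  )
  expr <- expression_matrix(vals, gene_ids = gid, sample_meta = meta)
  truth <- data.frame(gene_id = gid, inheritance_mode = mode,
                      mu1 = mu1, mu2 = mu2, f1_mean = f1_mean,
                      stringsAsFactors = FALSE)
  list(expression = expr, truth = truth)
}

#' Simulate block-correlated module expression with factor-driven traits
#'
#' Draws one latent factor per module per sample; a module gene is
#' loading * factor + sqrt(1 - loading^2) * unit Gaussian noise, so the
#' expected correlation between two module genes is loading^2. Background
#' genes are pure noise. Values are shifted onto a positive FPKM-like scale
#' (mean 10, unit sd; a location shift leaves every correlation untouched)
#' and floored at zero. Each kernel trait (FKW, DKW, TKL, TKW) is one module
#' factor plus Gaussian noise with sd \code{trait_noise_sd}, attached per
#' sample.
#'
#' @param config A \code{\link{simulation_config}}. If
#'   \code{hubs_per_module > 0}, the first genes of each module are planted
#'   at \code{hub_loading}.
#' @return A list with \code{expression} (an expression matrix object),
#'   \code{traits} (samples x traits data frame), \code{factors} (the latent
#'   module factors, modules x samples), and \code{truth} (per-gene module
#'   label, "unassigned" for background, and an \code{is_hub} flag).
#' @export
simulate_module_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genes_per_module < 50L)
    warning("genes_per_module < 50: planted modules fall below the minimum ",
            "detectable module size")
  if (config$hubs_per_module > config$genes_per_module)
    stop("'hubs_per_module' cannot exceed 'genes_per_module'")
  set.seed(config$seed + 2L)
  m <- config$n_modules
  gpm <- config$genes_per_module
  nb <- config$n_background_genes
  ns <- config$n_samples

  factors <- matrix(stats::rnorm(m * ns), nrow = m)
  rownames(factors) <- paste0("factor_", seq_len(m))

  n_genes <- m * gpm + nb
  vals <- matrix(0, nrow = n_genes, ncol = ns)
  module <- character(n_genes)
  is_hub <- logical(n_genes)
  row <- 0L
  for (k in seq_len(m)) {
    for (g in seq_len(gpm)) {
      row <- row + 1L
      lam <- if (g <= config$hubs_per_module) config$hub_loading
             else config$factor_loading
      vals[row, ] <- lam * factors[k, ] +
        sqrt(1 - lam^2) * stats::rnorm(ns)
      module[row] <- paste0("module_", k)
      is_hub[row] <- g <= config$hubs_per_module
    }
  }
  if (nb > 0L) {
    vals[(row + 1L):n_genes, ] <- stats::rnorm(nb * ns)
    module[(row + 1L):n_genes] <- "unassigned"
  }
  vals <- pmax(vals + 10, 0)   # positive FPKM-like scale; correlations unchanged

  gid <- sprintf("gene_%04d", seq_len(n_genes))
  meta <- data.frame(
    sample = sprintf("MIX_S1_%d", seq_len(ns)),
    genotype = "MIX", stage = "S1", replicate = seq_len(ns),
    stringsAsFactors = FALSE
  )
  expr <- expression_matrix(vals, gene_ids = gid, sample_meta = meta)

  trait_names <- c("FKW", "DKW", "TKL", "TKW")
  n_traits <- min(length(trait_names), m)
  traits <- as.data.frame(lapply(seq_len(n_traits), function(k) {
    factors[k, ] + stats::rnorm(ns, 0, config$trait_noise_sd)
  }))
  names(traits) <- trait_names[seq_len(n_traits)]
  rownames(traits) <- meta$sample

  truth <- data.frame(gene_id = gid, module = module, is_hub = is_hub,
                      stringsAsFactors = FALSE)
  list(expression = expr, traits = traits, factors = factors, truth = truth)
}
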