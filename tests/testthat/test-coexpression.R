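random_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  vals <- matrix(rlnorm(n_genes * n_samples, 1, 0.6), nrow = n_genes)
  meta <- data.frame(sample = sprintf("X_S1_%d", seq_len(n_samples)),
                     genotype = "X", stage = "S1",
                     replicate = seq_len(n_samples),
                     stringsAsFactors = FALSE)
  expression_matrix(vals, sprintf("g%03d", seq_len(n_genes)), meta)
}

test_that("network gene filter is strict at the threshold", {
  vals <- matrix(rep(c(1.01, 1.00, 0.5, 2, 3, 0.9, 1.2, 5, 0.1, 1.0001),
                     each = 6), nrow = 10, byrow = TRUE)
  m <- make_expr(vals, c("A", "B"))
  f <- filter_network_genes(m)
  expect_equal(nrow(f$values), 6)           # counted by hand: rows 1,4,5,7,8,10
  expect_true("g001" %in% rownames(f$values))
  expect_false("g002" %in% rownames(f$values))  # mean exactly 1 removed
  expect_error(filter_network_genes(make_expr(matrix(0.1, 2, 4),
                                              c("A", "B"))), "no gene")
})

test_that("adjacency matches the brute-force |cor|^beta loop", {
  m <- random_expr(20, 10, seed = 41)
  beta <- 6
  a <- compute_adjacency(m, beta)
  brute <- matrix(1, 20, 20)
  for (i in 1:20) for (j in 1:20) if (i != j)
    brute[i, j] <- abs(cor(m$values[i, ], m$values[j, ]))^beta
  expect_lt(max(abs(a - brute)), 1e-12)
  expect_lt(max(abs(a - t(a))), 1e-12)
  expect_true(all(diag(a) == 1))
  expect_true(all(a >= 0 & a <= 1))
  # identical genes are fully adjacent at any power
  dup <- m; dup$values[2, ] <- dup$values[1, ] * 3
  expect_equal(compute_adjacency(dup, 9)[1, 2], 1, tolerance = 1e-12)
  # arithmetic spot check via a constructed correlation
  expect_equal(0.5^2, 0.25)
  flat <- m; flat$values[3, ] <- 7
  expect_warning(compute_adjacency(flat, 2), "zero-variance")
})

test_that("TOM matches the triple-loop oracle and its closed forms", {
  m <- random_expr(15, 8, seed = 43)
  a <- compute_adjacency(m, 2)
  tom <- compute_tom(a)
  n <- nrow(a)
  brute <- matrix(1, n, n)
  k <- rowSums(a) - 1
  for (i in 1:n) for (j in 1:n) if (i != j) {
    s <- 0
    for (u in 1:n) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    brute[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  expect_lt(max(abs(tom - brute)), 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_lt(max(abs(tom - t(tom))), 1e-12)
  # disconnected graph: no shared neighbours, no overlap
  iso <- diag(1, 6)
  expect_true(all(compute_tom(iso)[upper.tri(iso)] == 0))
  # full clique: overlap is exactly 1 everywhere
  clique <- matrix(1, 7, 7)
  expect_equal(unname(compute_tom(clique)), matrix(1, 7, 7),
               tolerance = 1e-12)
})

test_that("eigengenes behave as first principal components", {
  m <- random_expr(30, 12, seed = 47)
  # module of identical profiles: variance fully explained
  prof <- m$values[1, ]
  for (i in 2:5) m$values[i, ] <- prof * i
  eg <- compute_eigengene(m, sprintf("g%03d", 1:5))
  expect_equal(eg$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$scores, prof)), 1, tolerance = 1e-10)
  expect_equal(sum(eg$scores^2), 1, tolerance = 1e-12)
  # sign convention survives flipping all values
  flip <- m; flip$values[1:5, ] <- -flip$values[1:5, ] + 20
  eg2 <- compute_eigengene(flip, sprintf("g%03d", 1:5))
  expect_gte(cor(eg2$scores, colMeans(t(scale(t(flip$values[1:5, ]))))), 0)
  # planted factor is tracked closely at loading 0.9
  sim <- simulate_module_expression(simulation_config(seed = 5))
  eg3 <- compute_eigengene(sim$expression,
                           sim$truth$gene_id[sim$truth$module == "module_1"])
  expect_gte(abs(cor(eg3$scores, sim$factors["factor_1", ])), 0.95)
})

test_that("planted modules are recovered and near-duplicates merged", {
  sim <- simulate_module_expression(simulation_config(seed = 11))
  net <- filter_network_genes(sim$expression)
  det <- detect_modules(net, beta = 9)
  expect_equal(ncol(det$eigengenes), 5)
  truth <- sim$truth$module[match(det$assignment$gene_id, sim$truth$gene_id)]
  planted <- truth != "unassigned"
  tab <- table(truth[planted], det$assignment$module[planted])
  expect_true(all(apply(tab, 1, max) / rowSums(tab) >= 0.9))
  # merging is stable: every remaining eigengene pair is separated
  d <- 1 - cor(det$eigengenes)
  expect_true(all(d[upper.tri(d)] >= 0.15))

  # two modules driven by nearly identical factors collapse into one
  cfg <- simulation_config(seed = 19, n_modules = 2, genes_per_module = 60,
                           factor_loading = 0.95, n_background_genes = 0)
  sim2 <- simulate_module_expression(cfg)
  f <- sim2$factors
  mix <- 0.97 * f[1, ] + sqrt(1 - 0.97^2) * f[2, ]  # cor ~0.97 with factor 1
  vals <- sim2$expression$values
  second <- sim2$truth$module == "module_2"
  lam <- 0.95
  set.seed(20)
  vals[second, ] <- lam * matrix(mix, sum(second), ncol(vals), byrow = TRUE) +
    sqrt(1 - lam^2) * matrix(rnorm(sum(second) * ncol(vals)), sum(second)) + 10
  m2 <- expression_matrix(pmax(vals, 0), rownames(vals), sim2$expression$meta)
  det2 <- detect_modules(m2, beta = 9)
  expect_equal(ncol(det2$eigengenes), 1)
})

test_that("gene order never affects the network analysis", {
  sim <- simulate_module_expression(
    simulation_config(seed = 29, n_modules = 2, genes_per_module = 50,
                      n_background_genes = 20))
  m <- sim$expression
  set.seed(30)
  perm <- sample(nrow(m$values))
  mp <- expression_matrix(m$values[perm, ], rownames(m$values)[perm], m$meta)
  a <- compute_adjacency(m, 9); ap <- compute_adjacency(mp, 9)
  expect_equal(ap, a[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
  det <- detect_modules(m, beta = 9)
  detp <- detect_modules(mp, beta = 9)
  co <- function(d) {
    mod <- d$assignment$module[order(d$assignment$gene_id)]
    outer(mod, mod, "==") & mod != "unassigned"
  }
  expect_identical(co(det), co(detp))
})

test_that("module-trait correlation flags exact and null traits correctly", {
  sim <- simulate_module_expression(simulation_config(seed = 31))
  det <- detect_modules(filter_network_genes(sim$expression), beta = 9)
  eg <- det$eigengenes[, 1]
  traits <- data.frame(exact = eg, anti = -eg,
                       row.names = rownames(det$eigengenes))
  mt <- module_trait_correlation(det$eigengenes, traits)
  self <- mt[mt$module == colnames(det$eigengenes)[1], ]
  expect_equal(self$r[self$trait == "exact"], 1, tolerance = 1e-10)
  expect_equal(self$r[self$trait == "anti"], -1, tolerance = 1e-10)
  expect_true(all(self$significant))
  # null traits: false-positive rate near the 5% level
  set.seed(32)
  fp <- mean(replicate(400, {
    y <- rnorm(length(eg))
    cor.test(eg, y)$p.value < 0.05
  }))
  expect_lt(abs(fp - 0.05), 0.035)
  # missing values are handled pairwise-complete
  tr2 <- data.frame(t1 = c(NA, eg[-1]))
  mt2 <- module_trait_correlation(det$eigengenes, tr2)
  expect_equal(mt2$n[mt2$module == colnames(det$eigengenes)[1]],
               length(eg) - 1)
})

test_that("hub connectivity matches the double-loop oracle", {
  sim <- simulate_module_expression(
    simulation_config(seed = 37, n_modules = 1, genes_per_module = 60,
                      n_background_genes = 0, hubs_per_module = 10))
  m <- sim$expression
  assign <- data.frame(gene_id = rownames(m$values), module = "M1",
                       stringsAsFactors = FALSE)
  hubs <- extract_hubs(m, assign, beta = 9)
  expect_equal(nrow(hubs), 30)
  expect_true(all(diff(hubs$k) <= 1e-12))
  a <- compute_adjacency(m, 9)
  for (i in c(1, 15, 30)) {
    g <- hubs$gene_id[i]
    expect_equal(hubs$k[i], sum(a[g, ]) - 1, tolerance = 1e-12)
  }
  planted <- sim$truth$gene_id[sim$truth$is_hub]
  expect_gte(sum(planted %in% hubs$gene_id), 9)
  # a gene duplicating every profile is the strongest hub
  dup <- m; dup$values[5, ] <- colMeans(dup$values[-5, ])
  a2 <- compute_adjacency(dup, 2)
  k2 <- rowSums(a2) - 1
  hub2 <- extract_hubs(dup, assign, beta = 2)
  expect_equal(hub2$gene_id[1], names(which.max(k2)))
  # modules smaller than top_n are returned whole
  small <- extract_hubs(m, transform(assign,
                                     module = ifelse(seq_len(60) <= 5,
                                                     "M1", "unassigned")),
                        beta = 9)
  expect_equal(nrow(small), 5)
})

test_that("edge export is thresholded, undirected and deterministic", {
  clique <- matrix(1, 5, 5)
  dimnames(clique) <- list(letters[1:5], letters[1:5])
  tom <- compute_tom(clique)
  edges <- export_network(tom, weight_threshold = 0.2)
  expect_equal(nrow(edges), choose(5, 2))
  expect_true(all(edges$weight == 1))
  expect_equal(nrow(export_network(tom, weight_threshold = 1.01)), 0)
  # each unordered pair appears exactly once
  keys <- apply(edges[c("source", "target")], 1,
                function(r) paste(sort(r), collapse = "|"))
  expect_false(any(duplicated(keys)))
  expect_true(all(edges$source < edges$target))
})
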