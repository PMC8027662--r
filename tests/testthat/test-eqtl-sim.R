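test_that("synthetic genotypes follow Hardy-Weinberg at their MAFs", {
  g <- simulate_genotypes(2000, 40, maf_range = c(0.1, 0.4), ld_rho = 0,
                          seed = 81)
  maf <- attr(g, "maf")
  expect_true(all(g %in% 0:2))
  # allele-frequency and variance checks, 4 binomial sd
  for (j in seq_len(ncol(g))) {
    expect_lt(abs(mean(g[, j]) - 2 * maf[j]),
              4 * sqrt(2 * maf[j] * (1 - maf[j]) / 2000))
  }
  v_expected <- 2 * maf * (1 - maf)
  expect_lt(max(abs(apply(g, 2, var) - v_expected) / v_expected), 0.25)
  # no LD requested: adjacent genotype correlations near zero
  adj <- sapply(2:ncol(g), function(j) cor(g[, j - 1], g[, j]))
  expect_lt(max(abs(adj)), 4 / sqrt(2000) * 1.5)
  # AR(1) LD present when requested
  g2 <- simulate_genotypes(2000, 40, ld_rho = 0.7, seed = 82)
  adj2 <- sapply(2:ncol(g2), function(j) cor(g2[, j - 1], g2[, j]))
  expect_gt(mean(adj2), 0.25)
  expect_error(simulate_genotypes(100, 5, maf_range = c(0, 0.4)), "maf_range")
  expect_error(simulate_genotypes(100, 5, maf_range = c(0.1, 0.6)), "maf_range")
})

test_that("expression realizes the requested heritability exactly", {
  g <- simulate_genotypes(500, 30, seed = 91)
  sim <- simulate_expression(g, n_causal = 5, h2 = 0.4, seed = 92)
  expect_equal(var(sim$expression), 1, tolerance = 1e-10)
  gcomp <- as.vector(g[, sim$causal_snps] %*% sim$beta)
  expect_equal(var(gcomp), 0.4, tolerance = 1e-10)
  expect_equal(length(sim$causal_snps), 5)
  # strong single eQTL: Wald statistic far above the genome-wide cutoff
  g3 <- simulate_genotypes(2000, 10, seed = 93)
  s3 <- simulate_expression(g3, n_causal = 1, h2 = 0.8, seed = 94)
  scan3 <- marginal_scan(g3, s3$expression)
  expect_gt(scan3$w[s3$causal_snps], 10 * 29.71679)  # ncp ~ N h2/(1-h2) = 8000
  expect_error(simulate_expression(g, 5, 1), "h2")
  expect_error(simulate_expression(g, 0, 0.4), "causal")
})

test_that("null expression gives uniform scan p-values", {
  set.seed(101)
  ps <- unlist(lapply(1:40, function(i) {
    g <- simulate_genotypes(200, 25, ld_rho = 0, seed = NULL)
    e <- simulate_expression(g, n_causal = 0, h2 = 0, seed = NULL)
    marginal_scan(g, e$expression)$p
  }))
  expect_lt(abs(mean(ps < 0.05) - 0.05), mc_tol_prop(0.05, length(ps)))
})

test_that("marginal_scan reproduces OLS and flags degenerate SNPs", {
  g <- simulate_genotypes(150, 8, seed = 111)
  e <- simulate_expression(g, 2, 0.3, seed = 112)
  scan <- marginal_scan(g, e$expression)
  # lm() as the independent reference on a few columns
  for (j in c(1, 4, 8)) {
    fit <- summary(lm(e$expression ~ g[, j]))$coefficients
    expect_equal(scan$beta_hat[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(scan$se[j], fit[2, 2], tolerance = 1e-10)
  }
  expect_equal(scan$beta_hat, cov(g, e$expression)[, 1] / apply(g, 2, var),
               tolerance = 1e-10)
  # constant column flagged, not fatal; noise-free fit underflows p
  g2 <- cbind(g[, 1:2], const = 1L)
  scan2 <- marginal_scan(g2, e$expression)
  expect_true(is.na(scan2$p[3]))
  scan3 <- marginal_scan(g[, 1, drop = FALSE], as.numeric(g[, 1]))
  expect_lt(scan3$p[1], 1e-100)
})

test_that("instrument selection takes the top SNP with deterministic ties", {
  scan <- data.frame(snp = c("a", "b", "c"),
                     p = c(0.2, 1e-9, 1e-9), w = c(1, 40, 40))
  expect_equal(select_instrument(scan, 5e-8), 2L)      # tie -> lower index
  expect_true(is.na(select_instrument(data.frame(p = c(0.1, 0.9)), 5e-8)))
  expect_equal(select_instrument(data.frame(p = c(0.5, 1e-10)), 5e-8), 2L)
  expect_error(select_instrument(data.frame(p = numeric(0))), "empty")
})

test_that("the null experiment enforces the selection floor and test ordering", {
  cfg <- gene_sim_config(n_individuals = 500, n_snps = 50, n_causal = 1,
                         h2 = 0.8, n_genes = 120, seed = 121)
  res <- run_smr_null_experiment(cfg)
  sel <- res$genes[res$genes$selected, ]
  expect_gt(res$n_selected, 60)
  expect_true(all(sel$w_gx >= p_to_chisq_threshold(cfg$p_select)))
  expect_true(all(sel$t_smr < pmin(sel$w_gx, sel$w_gy) + 1e-12))
  # rejection fractions ordered SMR <= min <= conditional at every level
  for (a in colnames(res$rejection)) {
    expect_lte(res$rejection["smr", a], res$rejection["min", a])
    expect_lte(res$rejection["min", a], res$rejection["conditional", a])
  }
  # determinism by seed
  res2 <- run_smr_null_experiment(cfg)
  expect_identical(res$genes, res2$genes)
  # results export round-trips through the tab-delimited table
  path <- tempfile(fileext = ".tsv")
  write_gene_results(res, path)
  back <- read.delim(path)
  expect_equal(nrow(back), cfg$n_genes)
  expect_equal(back$t_smr, res$genes$t_smr)
})

test_that("an unselectable configuration is flagged, not an error", {
  cfg <- gene_sim_config(n_individuals = 50, n_snps = 10, n_causal = 0,
                         h2 = 0, n_genes = 10, seed = 131)
  res <- run_smr_null_experiment(cfg)
  expect_equal(res$n_selected, 0)
  expect_null(res$rejection)
  expect_output(print(res), "no genes selected")
})
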