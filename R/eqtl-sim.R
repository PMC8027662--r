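#' Configuration for the synthetic cis-eQTL null-calibration experiment
#'
#' Bundles the generation parameters for [run_smr_null_experiment()]:
#' synthetic Hardy-Weinberg genotypes with AR(1) linkage disequilibrium
#' stand in for a real genotype panel, gene expression follows an
#' additive model at a specified narrow-sense heritability, and outcome
#' GWAS signals at selected instruments are null standard-normal draws.
#'
#' @param n_individuals eQTL-study sample size N (study grid 250, 500,
#'   1000, 2000; any positive value allowed).
#' @param n_snps cis-SNPs per gene.
#' @param n_causal Causal eQTLs per gene (grid 1, 5, 10); `<= n_snps`.
#' @param h2 Narrow-sense heritability of expression (grid 0.1, 0.2,
#'   0.4, 0.8); `0 <= h2 < 1`.
#' @param maf_range Minor-allele-frequency interval, bounds in (0, 0.5).
#' @param ld_rho Adjacent-SNP AR(1) correlation on the latent haplotype
#'   scale, in \code{[0, 1)}.
#' @param n_genes Number of genes to simulate.
#' @param p_select Instrument-selection p-value threshold.
#' @param alphas Nominal levels for the calibration summary.
#' @param seed Optional RNG seed for the whole experiment.
#' @return An object of class `"gene_sim_config"` (a validated list).
#' @examples
#' gene_sim_config(n_individuals = 500, n_genes = 100)
#' @export
gene_sim_config <- function(n_individuals = 1000, n_snps = 200, n_causal = 5,
                            h2 = 0.4, maf_range = c(0.05, 0.45),
                            ld_rho = 0.5, n_genes = 2000, p_select = 5e-8,
                            alphas = c(0.05, 0.01), seed = NULL) {
  stopifnot(n_individuals >= 4, n_snps >= 1, n_causal >= 0,
            n_causal <= n_snps, n_genes >= 1)
  if (h2 < 0 || h2 >= 1) stop("'h2' must lie in [0, 1)")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range >= 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("'maf_range' bounds must lie in (0, 0.5) and be ordered")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("'ld_rho' must lie in [0, 1)")
  if (p_select <= 0 || p_select > 1) stop("'p_select' must lie in (0, 1]")
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
         h2 = h2, maf_range = maf_range, ld_rho = ld_rho,
         n_genes = as.integer(n_genes), p_select = p_select,
         alphas = alphas, seed = seed),
    class = "gene_sim_config"
  )
}

#' @export
print.gene_sim_config <- function(x, ...) {
  cat("Synthetic eQTL experiment configuration\n")
  cat(sprintf("  N = %d individuals, %d genes, %d cis-SNPs/gene (AR(1) LD rho = %g)\n",
              x$n_individuals, x$n_genes, x$n_snps, x$ld_rho))
  cat(sprintf("  %d causal eQTLs, h2 = %g, MAF ~ U(%g, %g)\n",
              x$n_causal, x$h2, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  selection p < %g, seed = %s\n", x$p_select,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Synthetic Hardy-Weinberg genotypes with AR(1) linkage disequilibrium
#'
#' Each individual receives two haplotypes; each haplotype is a latent
#' standard-normal AR(1) sequence across SNPs thresholded at the normal
#' quantile of that SNP's minor-allele frequency, so every SNP is in
#' Hardy-Weinberg equilibrium at a MAF drawn uniformly from `maf_range`,
#' and adjacent SNPs are correlated through the latent scale. `ld_rho = 0`
#' gives independent SNPs.
#'
#' @param n_individuals Number of individuals (rows).
#' @param n_snps Number of SNPs (columns).
#' @param maf_range MAF interval, bounds in (0, 0.5).
#' @param ld_rho Latent adjacent-SNP correlation in \code{[0, 1)}.
#' @param seed Optional RNG seed; `NULL` draws from the ambient stream.
#' @return An integer matrix of 0/1/2 genotype counts with attribute
#'   `"maf"` (the per-SNP MAF used).
#' @examples
#' g <- simulate_genotypes(100, 10, seed = 1)
#' colMeans(g) / 2   # close to attr(g, "maf")
#' @export
simulate_genotypes <- function(n_individuals, n_snps,
                               maf_range = c(0.05, 0.45), ld_rho = 0.5,
                               seed = NULL) {
  stopifnot(n_individuals >= 1, n_snps >= 1)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range >= 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("'maf_range' bounds must lie in (0, 0.5) and be ordered")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("'ld_rho' must lie in [0, 1)")
  with_seed(seed, {
    maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    q <- stats::qnorm(maf)
    m <- 2L * n_individuals  # haplotypes
    lat <- matrix(stats::rnorm(m * n_snps), m, n_snps)
    if (ld_rho > 0 && n_snps > 1) {
      s <- sqrt(1 - ld_rho^2)
      for (j in 2:n_snps) lat[, j] <- ld_rho * lat[, j - 1] + s * lat[, j]
    }
    alleles <- lat < rep(q, each = m)  # minor-allele indicator per haplotype
    g <- alleles[seq_len(n_individuals), , drop = FALSE] +
      alleles[n_individuals + seq_len(n_individuals), , drop = FALSE]
    storage.mode(g) <- "integer"
    attr(g, "maf") <- maf
    g
  })
}

#' Simulate gene expression under an additive eQTL model
#'
#' Chooses `n_causal` causal SNPs uniformly without replacement, draws
#' their per-allele effects standard-normal, and forms
#' \eqn{x = \sum_j \beta_j g_j + e}. The realized genetic component is
#' rescaled so its sample variance is exactly `h2`, and the residual is
#' orthogonalized against it and rescaled to sample variance `1 - h2`, so
#' total expression variance is exactly 1 and the realized heritability is
#' `h2` by construction.
#'
#' @param genotypes Genotype matrix from [simulate_genotypes()].
#' @param n_causal Number of causal SNPs, `<= ncol(genotypes)`.
#' @param h2 Narrow-sense heritability, `0 <= h2 < 1`; `h2 > 0` requires
#'   `n_causal >= 1`.
#' @param seed Optional RNG seed; `NULL` draws from the ambient stream.
#' @return A list with `expression` (length-N vector, sample variance 1),
#'   `causal_snps` (column indices), `beta` (rescaled per-allele effects).
#' @examples
#' g <- simulate_genotypes(200, 20, seed = 1)
#' e <- simulate_expression(g, n_causal = 1, h2 = 0.4, seed = 2)
#' var(e$expression)
#' @export
simulate_expression <- function(genotypes, n_causal, h2, seed = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (h2 < 0 || h2 >= 1) stop("'h2' must lie in [0, 1)")
  if (n_causal > m) stop("'n_causal' exceeds the number of SNPs")
  if (h2 > 0 && n_causal < 1) stop("'h2' > 0 requires at least one causal SNP")
  with_seed(seed, {
    causal <- if (n_causal > 0) sort(sample.int(m, n_causal)) else integer(0)
    beta <- if (n_causal > 0) stats::rnorm(n_causal) else numeric(0)
    e <- stats::rnorm(n)
    if (h2 > 0) {
      gcomp <- as.vector(genotypes[, causal, drop = FALSE] %*% beta)
      gcomp <- gcomp - mean(gcomp)
      vg <- stats::var(gcomp)
      if (vg <= 0) stop("degenerate genetic component (constant causal genotypes)")
      scale_g <- sqrt(h2 / vg)
      gcomp <- gcomp * scale_g
      beta <- beta * scale_g
      e <- e - mean(e)
      e <- e - gcomp * sum(e * gcomp) / sum(gcomp^2)  # exact orthogonality
      e <- e * sqrt((1 - h2) / stats::var(e))
      x <- gcomp + e
    } else {
      beta <- rep(0, n_causal)
      e <- e - mean(e)
      x <- e / sqrt(stats::var(e))
    }
    list(expression = x, causal_snps = causal, beta = beta)
  })
}

#' Marginal association scan of every SNP against expression
#'
#' Simple linear regression of expression on each genotype column:
#' closed-form OLS slope, standard error, Wald statistic on the
#' chi-square scale, and two-sided p-value. Constant genotype columns are
#' flagged (`NA` row) and skipped, not fatal.
#'
#' @param genotypes Genotype matrix (individuals by SNPs).
#' @param expression Expression vector, `length(expression) == nrow(genotypes)`.
#' @return A `data.frame` with one row per SNP: `snp`, `beta_hat`, `se`,
#'   `w`, `p`, `n`.
#' @examples
#' g <- simulate_genotypes(200, 10, seed = 1)
#' e <- simulate_expression(g, 1, 0.4, seed = 2)
#' head(marginal_scan(g, e$expression))
#' @export
marginal_scan <- function(genotypes, expression) {
  n <- nrow(genotypes)
  if (length(expression) != n) stop("dimension mismatch between genotypes and expression")
  if (n < 3) stop("need at least 3 individuals for a slope standard error")
  xc <- expression - mean(expression)
  sxx <- sum(xc^2)
  gm <- colMeans(genotypes)
  sgg <- colSums(genotypes^2) - n * gm^2
  sgx <- as.vector(crossprod(genotypes, xc))
  ok <- sgg > 0
  beta_hat <- se <- w <- p <- rep(NA_real_, ncol(genotypes))
  beta_hat[ok] <- sgx[ok] / sgg[ok]
  sse <- pmax(sxx - beta_hat[ok]^2 * sgg[ok], 0)
  se[ok] <- sqrt(sse / (n - 2) / sgg[ok])
  w[ok] <- ifelse(se[ok] > 0, (beta_hat[ok] / se[ok])^2, Inf)
  p[ok] <- chisq_upper_p(pmin(w[ok], .Machine$double.xmax))
  snp <- colnames(genotypes)
  if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(genotypes)))
  data.frame(snp = snp, beta_hat = beta_hat, se = se, w = w, p = p, n = n,
             stringsAsFactors = FALSE)
}

#' Select the top instrument from a marginal scan
#'
#' Returns the index of the SNP with the smallest p-value if that p-value
#' is below `p_select`, otherwise `NA`. Ties are broken by the smallest
#' index; SNPs flagged `NA` in the scan are ignored.
#'
#' @param scan A scan `data.frame` from [marginal_scan()].
#' @param p_select Selection threshold, default genome-wide `5e-8`.
#' @return Integer index of the selected SNP, or `NA_integer_`.
#' @export
select_instrument <- function(scan, p_select = 5e-8) {
  if (nrow(scan) == 0L) stop("empty scan")
  p <- scan$p
  if (all(is.na(p))) return(NA_integer_)
  top <- which.min(p)  # ties and NAs: first minimal finite p
  if (p[top] < p_select) as.integer(top) else NA_integer_
}

#' Null-calibration experiment for the SMR test on synthetic eQTL genes
#'
#' For each gene: simulate genotypes and expression, scan all cis-SNPs,
#' select the top SNP if it reaches `p_select`; for selected genes draw a
#' null outcome-GWAS z-score (standard normal, independent of the eQTL
#' study), set \eqn{W_{gy} = z^2}, and compute the SMR, min-, and
#' conditional-test p-values. Since \eqn{b_{gy} = 0} for every gene, all
#' rejections are false positives: the summary reports the rejection
#' fraction of each test at the nominal levels, exposing the SMR test's
#' conservativeness under instrument selection while the conditional test
#' stays calibrated.
#'
#' @param config A [gene_sim_config()] object.
#' @return An object of class `"smr_null_experiment"`: list with `genes`
#'   (per-gene `data.frame`), `n_selected`, `rejection` (matrix of
#'   rejection fractions, tests by alpha levels, among selected genes;
#'   `NA` if none selected), `qq_pairs` (SMR statistics against 1-df
#'   chi-square quantiles), and `config`.
#' @examples
#' cfg <- gene_sim_config(n_individuals = 500, n_snps = 50, n_causal = 1,
#'                        h2 = 0.8, n_genes = 50, seed = 1)
#' run_smr_null_experiment(cfg)
#' @export
run_smr_null_experiment <- function(config) {
  if (!inherits(config, "gene_sim_config")) {
    stop("'config' must be a gene_sim_config object")
  }
  with_seed(config$seed, {
    rows <- vector("list", config$n_genes)
    for (g in seq_len(config$n_genes)) {
      geno <- simulate_genotypes(config$n_individuals, config$n_snps,
                                 config$maf_range, config$ld_rho, seed = NULL)
      sim <- simulate_expression(geno, config$n_causal, config$h2, seed = NULL)
      scan <- marginal_scan(geno, sim$expression)
      top <- select_instrument(scan, config$p_select)
      selected <- !is.na(top)
      if (selected) {
        z_gy <- stats::rnorm(1)
        w_gx <- scan$w[top]
        w_gy <- z_gy^2
        smr <- smr_statistic(w_gx, w_gy)
        mn <- min_test(w_gx, w_gy)
        rows[[g]] <- data.frame(
          gene = g, top_snp = top, b_gx = scan$beta_hat[top],
          se_gx = scan$se[top], p_gx = scan$p[top], w_gx = w_gx,
          selected = TRUE, z_gy = z_gy, w_gy = w_gy,
          t_smr = smr$statistic, p_smr = smr$p, p_min = mn$p,
          p_conditional = chisq_upper_p(w_gy))
      } else {
        rows[[g]] <- data.frame(
          gene = g, top_snp = NA_integer_, b_gx = NA_real_, se_gx = NA_real_,
          p_gx = min(scan$p, na.rm = TRUE), w_gx = NA_real_,
          selected = FALSE, z_gy = NA_real_, w_gy = NA_real_,
          t_smr = NA_real_, p_smr = NA_real_, p_min = NA_real_,
          p_conditional = NA_real_)
      }
    }
    genes <- do.call(rbind, rows)
    sel <- genes[genes$selected, , drop = FALSE]
    n_sel <- nrow(sel)
    rejection <- if (n_sel > 0) {
      r <- sapply(config$alphas, function(a) c(
        smr = mean(sel$p_smr < a),
        min = mean(sel$p_min < a),
        conditional = mean(sel$p_conditional < a)))
      colnames(r) <- as.character(config$alphas)
      r
    } else NULL
    qq <- if (n_sel > 0) qq_points(sel$t_smr, "chisq1") else NULL
    structure(
      list(genes = genes, n_selected = n_sel, rejection = rejection,
           qq_pairs = qq, config = config),
      class = "smr_null_experiment"
    )
  })
}

#' @export
print.smr_null_experiment <- function(x, ...) {
  cfg <- x$config
  cat("SMR null-calibration experiment on synthetic eQTL genes\n")
  cat(sprintf("  N = %d, %d genes, %d causal eQTLs, h2 = %g\n",
              cfg$n_individuals, cfg$n_genes, cfg$n_causal, cfg$h2))
  cat(sprintf("  genes with a selected instrument: %d (%.1f%%)\n",
              x$n_selected, 100 * x$n_selected / cfg$n_genes))
  if (is.null(x$rejection)) {
    cat("  no genes selected: calibration summary unavailable\n")
  } else {
    cat("  false-positive fraction among selected genes:\n")
    for (a in colnames(x$rejection)) {
      cat(sprintf("    alpha = %-5s SMR %.4f | min %.4f | conditional %.4f\n",
                  a, x$rejection["smr", a], x$rejection["min", a],
                  x$rejection["conditional", a]))
    }
  }
  invisible(x)
}

#' @export
plot.smr_null_experiment <- function(x, ...) {
  if (is.null(x$qq_pairs)) stop("no selected genes to plot")
  plot(x$qq_pairs$reference, x$qq_pairs$sample,
       xlab = "1-df chi-square quantiles", ylab = "SMR statistic quantiles",
       main = "SMR null calibration under instrument selection", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write per-gene experiment results as a tab-delimited table
#'
#' @param x An `"smr_null_experiment"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(x, path) {
  if (!inherits(x, "smr_null_experiment")) stop("'x' must be an smr_null_experiment")
  utils::write.table(x$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
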