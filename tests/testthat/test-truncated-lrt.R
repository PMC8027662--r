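test_that("truncated log-likelihood matches direct evaluation", {
  z <- 0.19; mu <- 0.15; s <- 1 / sqrt(997); cc <- 0.17171315
  direct <- log(dnorm((z - mu) / s) / s) -
    log(1 - pnorm((cc - mu) / s))
  expect_equal(truncated_normal_loglik(z, mu, s, cc), direct, tolerance = 1e-12)
  # no truncation: plain normal log density
  expect_equal(truncated_normal_loglik(z, mu, s, -Inf),
               dnorm(z, mu, s, log = TRUE))
  # finite cutoff always costs: the denominator 1 - Phi < 1
  expect_lt(dnorm(z, z, s, log = TRUE),
            truncated_normal_loglik(z, z, s, cc))
  expect_error(truncated_normal_loglik(0.1, 0, s, 0.2), "selection")
  expect_error(truncated_normal_loglik(0.1, 0, -1, 0), "sd")
})

test_that("conditional MLE shrinks below the naive estimate and matches the grid oracle", {
  s <- 1 / sqrt(997)
  cc <- fisher_cutoff_oracle(5e-8, 1000)
  # untruncated: MLE is the observation itself
  expect_equal(mle_mu_truncated(0.19, s, -Inf)$mu_hat, 0.19, tolerance = 1e-8)
  for (z in c(0.185, 0.19, 0.23, 0.35)) {
    fit <- mle_mu_truncated(z, s, cc)
    expect_true(fit$converged)
    expect_lt(fit$mu_hat, z)                      # winner's-curse correction
    expect_lt(abs(fit$mu_hat - grid_mle_oracle(z, s, cc)), 1e-4)
  }
  # two untruncated observations, common mean: inverse-variance weights
  z <- c(0.2, 0.1); ss <- c(0.02, 0.05)
  fit <- mle_mu_truncated(z, ss, -Inf, common_mean = TRUE)
  expect_equal(fit$mu_hat, sum(z / ss^2) / sum(1 / ss^2), tolerance = 1e-8)
  expect_error(mle_mu_truncated(0.1, s, 0.2), "selection")
})

test_that("the LRT is non-negative, zero under symmetry, and classical without truncation", {
  sym <- steiger_truncated_lrt(0.21, 0.21, 1000, 1000)
  expect_equal(sym$lrt_stat, 0, tolerance = 1e-8)

  set.seed(51)
  for (i in 1:20) {
    nx <- sample(500:5000, 1); ny <- sample(500:5000, 1)
    cx <- fisher_cutoff_oracle(5e-8, nx); cy <- fisher_cutoff_oracle(5e-8, ny)
    zx <- cx + rexp(1, 20); zy <- cy + rexp(1, 20)
    fit <- steiger_truncated_lrt(zx, zy, nx, ny, c_gx = cx, c_gy = cy)
    expect_gte(fit$lrt_stat, 0)
    expect_true(fit$converged)
  }

  # cutoffs far below the data: the statistic collapses to T_Steiger^2
  nx <- 1000; ny <- 10000
  zx <- 0.21; zy <- 0.16
  sx <- 1 / sqrt(nx - 3); sy <- 1 / sqrt(ny - 3)
  fit <- steiger_truncated_lrt(zx, zy, nx, ny,
                               c_gx = zx - 20 * sx, c_gy = zy - 20 * sy)
  t2 <- ((zx - zy) / sqrt(sx^2 + sy^2))^2
  expect_equal(fit$lrt_stat, t2, tolerance = 1e-6)
  expect_equal(fit$mu_gx_hat, zx, tolerance = 1e-6)
  expect_equal(fit$mu_gy_hat, zy, tolerance = 1e-6)
  expect_error(steiger_truncated_lrt(0.1, 0.2, 1000, 10000), "selection")
})

test_that("conditional MLE shrinks the winner's-curse bias in the median", {
  # truncated draws at the rho = 0.15, n_x = 1000 selection settings.
  # With a single observation per study the MLE has no finite expectation
  # (observations just above the cutoff send it far below z), so the
  # bias-correction claim is about typical values: the median of mu_hat
  # is closer to the true mean than the median of the naive z.
  mu <- fisher_z(0.15); s <- 1 / sqrt(997)
  cc <- fisher_cutoff_oracle(5e-8, 1000)
  set.seed(61)
  u <- runif(400, pnorm(cc, mu, s), 1)
  z <- qnorm(u, mu, s)
  mu_hat <- vapply(z, function(zz) mle_mu_truncated(zz, s, cc)$mu_hat, numeric(1))
  expect_lt(abs(median(mu_hat) - mu), abs(median(z) - mu))
  # every corrected estimate sits below its naive counterpart
  expect_true(all(mu_hat < z))
})

test_that("bootstrap reference for the LRT is calibrated under the null", {
  mu <- fisher_z(0.15)
  sx <- 1 / sqrt(997); sy <- 1 / sqrt(9997)
  cx <- fisher_cutoff_oracle(5e-8, 1000); cy <- fisher_cutoff_oracle(5e-8, 10000)
  set.seed(71)
  n_rep <- 120
  zx <- qnorm(runif(n_rep, pnorm(cx, mu, sx), 1), mu, sx)
  zy <- qnorm(runif(n_rep, pnorm(cy, mu, sy), 1), mu, sy)
  p_boot <- vapply(seq_len(n_rep), function(i) {
    steiger_truncated_lrt(zx[i], zy[i], 1000, 10000, c_gx = cx, c_gy = cy,
                          p_method = "bootstrap", n_boot = 99,
                          seed = 1000 + i)$p
  }, numeric(1))
  rej <- mean(p_boot < 0.05)
  expect_lt(abs(rej - 0.05), mc_tol_prop(0.05, n_rep))
})
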