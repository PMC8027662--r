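# Independent oracles used across the suite. Each recomputes the target
# quantity from first principles (closed forms, quadrature, dense grids)
# without calling the package code paths it checks.

# Exceedance probability of a noncentral 1-df chi-square (Z + sqrt(ncp))^2
# above a cutoff, via the two normal tails.
chisq_selection_prob_oracle <- function(ncp, cutoff) {
  pnorm(sqrt(cutoff) - sqrt(ncp), lower.tail = FALSE) +
    pnorm(-sqrt(cutoff) - sqrt(ncp))
}

# Fisher-Z cutoff implied by a selection p-value at sample size n,
# written out independently of the package's selection_design chain.
fisher_cutoff_oracle <- function(p_threshold, n) {
  w <- qchisq(p_threshold, df = 1, lower.tail = FALSE)
  atanh(1 / sqrt(1 + (n - 2) / w))
}

# Mean of a normal(mu, s) left-truncated at cc.
truncnorm_mean_oracle <- function(mu, s, cc) {
  a <- (cc - mu) / s
  mu + s * dnorm(a) / pnorm(a, lower.tail = FALSE)
}

# Exact two-sided rejection probability of the Steiger statistic under
# pairwise selection with a common true correlation: quadrature over the
# truncated z_gx, closed normal probabilities for z_gy.
steiger_type1_oracle <- function(rho, n_x, n_y, p_threshold = 5e-8,
                                 alpha = 0.05) {
  mu <- atanh(rho)
  sx <- 1 / sqrt(n_x - 3); sy <- 1 / sqrt(n_y - 3)
  cx <- fisher_cutoff_oracle(p_threshold, n_x)
  cy <- fisher_cutoff_oracle(p_threshold, n_y)
  s <- sqrt(sx^2 + sy^2); crit <- qnorm(1 - alpha / 2)
  px <- pnorm(cx, mu, sx, lower.tail = FALSE)
  py <- pnorm(cy, mu, sy, lower.tail = FALSE)
  f <- function(zx) {
    p_pos <- pmax(pnorm(zx - crit * s, mu, sy) - pnorm(cy, mu, sy), 0)
    p_neg <- pnorm(pmax(zx + crit * s, cy), mu, sy, lower.tail = FALSE)
    dnorm(zx, mu, sx) / px * (p_pos + p_neg) / py
  }
  integrate(f, cx, Inf, rel.tol = 1e-10)$value
}

# Expected fraction of pairs passing both Fisher-Z cutoffs (product of
# independent normal upper tails), written out directly.
steiger_selection_prob_oracle <- function(rho, n_x, n_y, p_threshold = 5e-8) {
  mu <- atanh(rho)
  pnorm(fisher_cutoff_oracle(p_threshold, n_x), mu, 1 / sqrt(n_x - 3),
        lower.tail = FALSE) *
    pnorm(fisher_cutoff_oracle(p_threshold, n_y), mu, 1 / sqrt(n_y - 3),
          lower.tail = FALSE)
}

# Dense grid maximizer of the truncated-normal log-likelihood: the
# brute-force reference for the conditional MLE, resolution 1e-4.
grid_mle_oracle <- function(z, s, cc, step = 1e-4) {
  grid <- seq(z - 6 * s, z + 2 * s, by = step)
  ll <- dnorm(z, grid, s, log = TRUE) -
    pnorm(cc, grid, s, lower.tail = FALSE, log.p = TRUE)
  grid[which.max(ll)]
}

# Sample excess kurtosis, for tail diagnostics.
kurtosis_oracle <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}

# 4-sd Monte-Carlo tolerance for a binomial proportion.
mc_tol_prop <- function(p, n) 4 * sqrt(p * (1 - p) / n)
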