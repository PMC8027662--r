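#' Wald ratio (single-instrument 2SLS estimate of the causal effect)
#'
#' \eqn{\hat{b}_{xy} = \hat{b}_{gy} / \hat{b}_{gx}}: the ratio of the
#' SNP-outcome to the SNP-exposure effect estimate. Antisymmetric in the
#' sign of either argument.
#'
#' @param b_gy_hat SNP-outcome effect estimate. Vectorised.
#' @param b_gx_hat SNP-exposure effect estimate; must be nonzero.
#' @return The causal-effect estimate `b_gy_hat / b_gx_hat`.
#' @examples
#' wald_ratio(0.08, 0.4)
#' @export
wald_ratio <- function(b_gy_hat, b_gx_hat) {
  if (any(!is.finite(b_gx_hat)) || any(b_gx_hat == 0)) {
    stop("'b_gx_hat' must be nonzero: the Wald ratio is undefined for a ",
         "null instrument (weak-instrument degenerate case)")
  }
  b_gy_hat / b_gx_hat
}

#' SMR statistic and its nominal p-value
#'
#' \eqn{T_{SMR} = W_{gx} W_{gy} / (W_{gx} + W_{gy})}, half the harmonic
#' mean of the two Wald statistics, referred to a 1-df chi-square. Because
#' \eqn{T_{SMR} < \min(W_{gx}, W_{gy})} whenever both are positive, the
#' nominal chi-square reference makes the test conservative.
#'
#' @param w_gx,w_gy Wald statistics on the chi-square scale, `>= 0`.
#'   Vectorised. The degenerate pair (0, 0) is defined as statistic 0 with
#'   p = 1, the limit of the formula along `w_gx = w_gy -> 0`.
#' @return A list with `statistic` and `p`.
#' @examples
#' smr_statistic(29.71679, 29.71679)  # w/2 case
#' @export
smr_statistic <- function(w_gx, w_gy) {
  if (any(!is.finite(w_gx)) || any(!is.finite(w_gy)) ||
      any(w_gx < 0) || any(w_gy < 0)) {
    stop("Wald statistics must be non-negative and finite")
  }
  s <- w_gx + w_gy
  t <- ifelse(s == 0, 0, w_gx * w_gy / s)
  list(statistic = t, p = chisq_upper_p(t))
}

#' Min-test: reject iff both marginal associations are significant
#'
#' The statistic is \eqn{\min(W_{gx}, W_{gy})}; its p-value is the larger
#' of the two marginal 1-df chi-square p-values, so rejection at level
#' alpha occurs if and only if both Wald statistics are individually
#' significant. Strictly more powerful than the SMR test for the composite
#' null (either association absent), since \eqn{T_{SMR} < \min}.
#'
#' @param w_gx,w_gy Wald statistics, `>= 0`. Vectorised.
#' @return A list with `statistic` (the minimum) and `p` (max marginal p).
#' @examples
#' min_test(30, 40)
#' @export
min_test <- function(w_gx, w_gy) {
  if (any(!is.finite(w_gx)) || any(!is.finite(w_gy)) ||
      any(w_gx < 0) || any(w_gy < 0)) {
    stop("Wald statistics must be non-negative and finite")
  }
  list(statistic = pmin(w_gx, w_gy),
       p = pmax(chisq_upper_p(w_gx), chisq_upper_p(w_gy)))
}

#' Conditional test of the outcome association given instrument selection
#'
#' Once an instrument has passed exposure-side selection, the exposure
#' association is established and the meaningful null is that the
#' SNP-outcome effect is zero. The test statistic is \eqn{W_{gy}} alone,
#' referred to a 1-df chi-square, with Bonferroni correction over the
#' number of genes that contributed a selected instrument (a gene-level
#' rather than genome-wide threshold). Validity assumes the instrument
#' affects the outcome only through the exposure (no pleiotropy); this
#' assumption is documented, not checked.
#'
#' @param w_gy Wald statistic for the SNP-outcome association, `>= 0`.
#'   Vectorised.
#' @param m_genes Number of genes with a selected instrument (Bonferroni
#'   denominator), `>= 1`.
#' @param alpha Family-wise error level in (0, 1).
#' @return An object of class `"conditional_test"`: list with `p`,
#'   `threshold` (`alpha/m_genes`), `reject` (strict `p < threshold`),
#'   `m_genes`, `alpha`.
#' @examples
#' conditional_test(25, m_genes = 9639)   # threshold 0.05/9639 = 5.18726e-6
#' @export
conditional_test <- function(w_gy, m_genes = 1, alpha = 0.05) {
  if (any(!is.finite(w_gy)) || any(w_gy < 0)) {
    stop("'w_gy' must be non-negative and finite")
  }
  if (length(m_genes) != 1L || m_genes < 1) stop("'m_genes' must be >= 1")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)")
  }
  p <- chisq_upper_p(w_gy)
  thr <- alpha / m_genes
  structure(
    list(p = p, threshold = thr, reject = p < thr,
         m_genes = m_genes, alpha = alpha),
    class = "conditional_test"
  )
}

#' @export
print.conditional_test <- function(x, ...) {
  cat("Conditional test of the outcome association (W_gy)\n")
  cat(sprintf("  gene-level Bonferroni threshold: %.6g (alpha = %g over %d genes)\n",
              x$threshold, x$alpha, x$m_genes))
  if (length(x$p) == 1L) {
    cat(sprintf("  p = %.6g -> %s\n", x$p,
                if (x$reject) "reject" else "do not reject"))
  } else {
    cat(sprintf("  %d tests, %d rejected\n", length(x$p), sum(x$reject)))
  }
  invisible(x)
}

#' SMR analysis of one instrument: Wald ratio, SMR, min and conditional tests
#'
#' Convenience wrapper taking the exposure-side and outcome-side summary
#' statistics for a selected instrument and returning the Wald-ratio
#' causal-effect estimate together with the SMR statistic, the min-test,
#' and the conditional test.
#'
#' @param b_gx,se_gx SNP-exposure effect estimate and its standard error.
#' @param b_gy,se_gy SNP-outcome effect estimate and its standard error.
#' @param m_genes Bonferroni denominator for the conditional test.
#' @param alpha Level for the conditional test.
#' @return An object of class `"smr_test"`: list with `b_xy_hat`, `w_gx`,
#'   `w_gy`, `t_smr`, `p_smr`, `t_min`, `p_min`, `p_conditional`,
#'   `conditional_threshold`.
#' @examples
#' smr_test(b_gx = 0.6, se_gx = 0.1, b_gy = 0.05, se_gy = 0.02)
#' @export
smr_test <- function(b_gx, se_gx, b_gy, se_gy, m_genes = 1, alpha = 0.05) {
  w_gx <- wald_chisq(b_gx, se_gx)
  w_gy <- wald_chisq(b_gy, se_gy)
  smr <- smr_statistic(w_gx, w_gy)
  mn <- min_test(w_gx, w_gy)
  cond <- conditional_test(w_gy, m_genes = m_genes, alpha = alpha)
  structure(
    list(b_xy_hat = wald_ratio(b_gy, b_gx),
         w_gx = w_gx, w_gy = w_gy,
         t_smr = smr$statistic, p_smr = smr$p,
         t_min = mn$statistic, p_min = mn$p,
         p_conditional = cond$p, conditional_threshold = cond$threshold,
         m_genes = m_genes, alpha = alpha),
    class = "smr_test"
  )
}

#' @export
print.smr_test <- function(x, ...) {
  cat("Summary-data MR, single instrument\n")
  cat(sprintf("  Wald ratio b_xy      : %.6g\n", x$b_xy_hat[1]))
  cat(sprintf("  W_gx, W_gy           : %.4f, %.4f\n", x$w_gx[1], x$w_gy[1]))
  cat(sprintf("  SMR      T = %8.4f  p = %.4g\n", x$t_smr[1], x$p_smr[1]))
  cat(sprintf("  min-test T = %8.4f  p = %.4g\n", x$t_min[1], x$p_min[1]))
  cat(sprintf("  conditional (W_gy)   p = %.4g  (threshold %.4g)\n",
              x$p_conditional[1], x$conditional_threshold))
  if (length(x$b_xy_hat) > 1L) {
    cat(sprintf("  ... and %d more instruments\n", length(x$b_xy_hat) - 1L))
  }
  invisible(x)
}

#' Two-sample MR Steiger directionality test
#'
#' Compares the Fisher-Z transformed absolute sample correlations of the
#' instrument with exposure and with outcome:
#' \deqn{T = \frac{z_{gx} - z_{gy}}{\sqrt{1/(n_x-3) + 1/(n_y-3)}}}
#' referred to a standard normal. A significant positive statistic is read
#' as causal direction exposure-to-outcome; significant negative as
#' outcome-to-exposure; otherwise the direction is undetermined. Note that
#' under instrument selection the two z's are truncated normals and the
#' nominal N(0,1) reference can be liberal or conservative; see
#' [steiger_truncated_lrt()] for the selection-aware remedy.
#'
#' @param rho_gx_hat,rho_gy_hat Sample correlations of the SNP with the
#'   exposure and the outcome, `|rho| < 1`. Vectorised.
#' @param n_x,n_y Sample sizes of the two studies, `>= 4`.
#' @param alpha Two-sided level used to call the direction.
#' @return An object of class `"steiger_test"`: list with `t_steiger`,
#'   `p` (two-sided normal), `direction` (one of `"x_to_y"`, `"y_to_x"`,
#'   `"undetermined"`), `z_gx`, `z_gy`, `n_x`, `n_y`, `alpha`.
#' @examples
#' steiger_test(0.19, 0.15, n_x = 1000, n_y = 10000)
#' @export
steiger_test <- function(rho_gx_hat, rho_gy_hat, n_x, n_y, alpha = 0.05) {
  if (any(n_x < 4) || any(n_y < 4)) stop("sample sizes must be at least 4")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)")
  }
  z_gx <- fisher_z(rho_gx_hat)
  z_gy <- fisher_z(rho_gy_hat)
  res <- steiger_from_z(z_gx, z_gy, n_x, n_y, alpha = alpha)
  res$rho_gx_hat <- rho_gx_hat
  res$rho_gy_hat <- rho_gy_hat
  res
}

#' Steiger test from precomputed Fisher-Z values
#'
#' Same statistic as [steiger_test()] but taking the Fisher-Z transforms
#' directly; used by the selection simulators where the z's are the
#' simulated quantities.
#'
#' @param z_gx,z_gy Fisher-Z values. Vectorised.
#' @inheritParams steiger_test
#' @return An object of class `"steiger_test"`; see [steiger_test()].
#' @export
steiger_from_z <- function(z_gx, z_gy, n_x, n_y, alpha = 0.05) {
  if (any(n_x < 4) || any(n_y < 4)) stop("sample sizes must be at least 4")
  se <- sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  t <- (z_gx - z_gy) / se
  p <- 2 * stats::pnorm(abs(t), lower.tail = FALSE)
  direction <- rep("undetermined", length(t))
  direction[p < alpha & t > 0] <- "x_to_y"
  direction[p < alpha & t < 0] <- "y_to_x"
  structure(
    list(t_steiger = t, p = p, direction = direction,
         z_gx = z_gx, z_gy = z_gy, n_x = n_x, n_y = n_y, alpha = alpha),
    class = "steiger_test"
  )
}

#' @export
print.steiger_test <- function(x, ...) {
  cat("Two-sample MR Steiger test\n")
  cat(sprintf("  n_x = %d, n_y = %d\n", as.integer(x$n_x[1]), as.integer(x$n_y[1])))
  if (length(x$t_steiger) == 1L) {
    cat(sprintf("  z_gx = %.6f, z_gy = %.6f\n", x$z_gx, x$z_gy))
    cat(sprintf("  T = %.4f, two-sided p = %.4g\n", x$t_steiger, x$p))
    cat(sprintf("  inferred direction: %s (at alpha = %g)\n", x$direction, x$alpha))
  } else {
    cat(sprintf("  %d tests; directions: %s\n", length(x$t_steiger),
                paste(sprintf("%s=%d", names(table(x$direction)),
                              as.integer(table(x$direction))), collapse = ", ")))
  }
  invisible(x)
}
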