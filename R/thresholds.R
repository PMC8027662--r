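#' Wald statistic on the chi-square scale
#'
#' Squares the z-score of a summary-statistic effect estimate,
#' \eqn{W = (\hat{b}/SE)^2}. Under the null of no association \eqn{W}
#' follows a 1-df chi-square distribution.
#'
#' @param beta_hat Effect estimate (per-allele, trait units). Vectorised.
#' @param se Standard error of `beta_hat`; must be strictly positive.
#' @return The Wald statistic `(beta_hat/se)^2`, a non-negative numeric.
#' @examples
#' wald_chisq(0.5, 0.1)
#' wald_chisq(sqrt(13), 1)   # noncentrality-13 scale
#' @export
wald_chisq <- function(beta_hat, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("'se' must be strictly positive and finite")
  }
  (beta_hat / se)^2
}

#' Upper-tail p-value of the 1-df chi-square
#'
#' @param w Wald statistic(s) on the chi-square scale, `w >= 0`.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' chisq_upper_p(29.71679)   # ~ 5e-8, the genome-wide cutoff
#' @export
chisq_upper_p <- function(w) {
  if (any(!is.finite(w)) || any(w < 0)) stop("'w' must be non-negative and finite")
  stats::pchisq(w, df = 1, lower.tail = FALSE)
}

#' Chi-square cutoff for a p-value threshold
#'
#' Inverse of [chisq_upper_p()]: the 1-df chi-square upper quantile a Wald
#' statistic must exceed for its p-value to fall below `p`. For the usual
#' genome-wide threshold `p = 5e-8` this is 29.71679.
#'
#' @param p p-value threshold(s) in (0, 1].
#' @return The Wald cutoff, non-negative numeric.
#' @examples
#' p_to_chisq_threshold(5e-8)
#' @export
p_to_chisq_threshold <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("'p' must lie in (0, 1]")
  }
  stats::qchisq(p, df = 1, lower.tail = FALSE)
}

#' Smallest attainable absolute sample correlation under selection
#'
#' A SNP whose Wald statistic passes the cutoff `w_threshold` in a study of
#' `n` individuals must have absolute sample correlation with the phenotype
#' of at least \eqn{1/\sqrt{1 + (n-2)/W}}. Selection on significance
#' therefore imposes a floor on \eqn{|\hat\rho|}.
#'
#' @param w_threshold Wald cutoff on the chi-square scale, `> 0`.
#' @param n Sample size, `>= 3`. Vectorised.
#' @return Correlation floor in (0, 1), strictly decreasing in `n`.
#' @examples
#' wald_to_min_abs_corr(29.71679, c(100, 1000, 10000))
#' @export
wald_to_min_abs_corr <- function(w_threshold, n) {
  if (any(!is.finite(w_threshold)) || any(w_threshold <= 0)) {
    stop("'w_threshold' must be strictly positive")
  }
  if (any(n < 3)) stop("'n' must be at least 3")
  1 / sqrt(1 + (n - 2) / w_threshold)
}

#' Fisher-Z transformation of a correlation
#'
#' \eqn{z = \tfrac12 \log\{(1+|\rho|)/(1-|\rho|)\}}, approximately normal
#' with variance \eqn{1/(n-3)} for a sample correlation on `n` pairs. The
#' absolute value is taken by default, matching the two-sample MR Steiger
#' statistic; set `signed = TRUE` for the classical signed transform.
#'
#' @param rho Correlation(s), `|rho| < 1`.
#' @param signed If `TRUE`, transform `rho` itself rather than `|rho|`.
#' @return Fisher-Z value(s); non-negative unless `signed = TRUE`.
#' @examples
#' fisher_z(0.1700451)
#' fisher_z(-0.3, signed = TRUE)
#' @export
fisher_z <- function(rho, signed = FALSE) {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) stop("'rho' must satisfy |rho| < 1")
  r <- if (signed) rho else abs(rho)
  atanh(r)
}

#' Selection design: p-value threshold and its derived cutoffs
#'
#' Captures an instrument-selection rule (keep SNPs with association
#' p-value below `p_threshold`) together with the scales on which the
#' induced truncation acts: the chi-square cutoff on the Wald scale, the
#' per-sample-size floor on the absolute sample correlation, and the
#' corresponding Fisher-Z cutoff.
#'
#' @param p_threshold Selection p-value in (0, 1); default genome-wide
#'   significance `5e-8`.
#' @return An object of class `"selection_design"` with elements
#'   `p_threshold`, `w_threshold`, and functions `min_abs_corr(n)` and
#'   `fisher_z_cutoff(n)`.
#' @examples
#' d <- selection_design(5e-8)
#' d$w_threshold                 # 29.71679
#' d$min_abs_corr(1000)          # 0.1700451
#' d$fisher_z_cutoff(1000)       # 0.1717131
#' @export
selection_design <- function(p_threshold = 5e-8) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      !is.finite(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop("'p_threshold' must be a single p-value in (0, 1)")
  }
  w <- p_to_chisq_threshold(p_threshold)
  structure(
    list(
      p_threshold = p_threshold,
      w_threshold = w,
      min_abs_corr = function(n) wald_to_min_abs_corr(w, n),
      fisher_z_cutoff = function(n) fisher_z(wald_to_min_abs_corr(w, n))
    ),
    class = "selection_design"
  )
}

#' @export
print.selection_design <- function(x, ...) {
  cat("Instrument selection design\n")
  cat(sprintf("  p-value threshold : %g\n", x$p_threshold))
  cat(sprintf("  chi-square cutoff : %.5f (1 df)\n", x$w_threshold))
  cat("  correlation floor / Fisher-Z cutoff by sample size:\n")
  for (n in c(100, 1000, 10000)) {
    cat(sprintf("    n = %6d : |rho| >= %.7f, z >= %.8f\n",
                n, x$min_abs_corr(n), x$fisher_z_cutoff(n)))
  }
  invisible(x)
}
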