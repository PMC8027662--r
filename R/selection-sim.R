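# Run expr under a given seed, restoring the caller's .Random.seed
# afterwards so seeded simulators do not perturb the global stream. A NULL
# seed evaluates expr on the ambient stream (advancing it), so nested
# seed-NULL calls inside one seeded experiment draw sequentially.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Selection on noncentral chi-square Wald statistics
#'
#' Draws `n_total` independent Wald statistics as \eqn{(Z + \sqrt{ncp})^2}
#' with Z standard normal (a noncentral 1-df chi-square with noncentrality
#' `ncp`) and keeps those at or above `cutoff` — the winner's-curse
#' selection applied to instruments in the exposure study. With
#' noncentrality 13 and the genome-wide cutoff 29.71679, about 3.25% of
#' 10,000 draws survive.
#'
#' @param ncp Noncentrality parameter, `>= 0`.
#' @param cutoff Wald cutoff on the chi-square scale, `>= 0`.
#' @param n_total Number of draws, `>= 1`.
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `"chisq_selection_sim"`: list with `draws`
#'   (all Wald values), `selected` (subset `>= cutoff`), `n_selected`,
#'   `qq_pairs` (selected order statistics against an equal-size reference
#'   sample of fresh unselected draws, for quantile-quantile display),
#'   `ncp`, `cutoff`, `n_total`, `seed`.
#' @examples
#' sim <- simulate_chisq_selection(13, 29.71679, 10000, seed = 1)
#' sim$n_selected
#' @export
simulate_chisq_selection <- function(ncp, cutoff, n_total, seed = NULL) {
  if (length(ncp) != 1L || !is.finite(ncp) || ncp < 0) stop("'ncp' must be >= 0")
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff < 0) stop("'cutoff' must be >= 0")
  if (length(n_total) != 1L || !is.finite(n_total) || n_total < 1) stop("'n_total' must be >= 1")
  n_total <- as.integer(n_total)
  with_seed(seed, {
    draws <- (stats::rnorm(n_total) + sqrt(ncp))^2
    selected <- draws[draws >= cutoff]
    n_sel <- length(selected)
    # reference: fresh unselected draws from the same noncentral chi-square
    reference <- if (n_sel > 0) (stats::rnorm(n_sel) + sqrt(ncp))^2 else numeric(0)
    qq <- if (n_sel > 0) qq_points(selected, reference) else
      data.frame(reference = numeric(0), sample = numeric(0))
    structure(
      list(draws = draws, selected = selected, n_selected = n_sel,
           qq_pairs = qq, ncp = ncp, cutoff = cutoff, n_total = n_total,
           seed = seed),
      class = "chisq_selection_sim"
    )
  })
}

#' @export
print.chisq_selection_sim <- function(x, ...) {
  cat("Noncentral chi-square selection experiment\n")
  cat(sprintf("  ncp = %g, cutoff = %.5f, draws = %d\n", x$ncp, x$cutoff, x$n_total))
  cat(sprintf("  selected: %d (%.2f%%)\n", x$n_selected, 100 * x$n_selected / x$n_total))
  invisible(x)
}

#' @export
plot.chisq_selection_sim <- function(x, ...) {
  plot(x$qq_pairs$reference, x$qq_pairs$sample,
       xlab = "unselected reference quantiles", ylab = "selected Wald quantiles",
       main = "Selection on the Wald statistic", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(v = x$cutoff, col = "grey40")
  invisible(x)
}

#' Wald-ratio distribution with and without instrument selection
#'
#' Generates `n_total` pairs \eqn{\hat b_{gx} \sim N(b_{gx}, 1)},
#' \eqn{\hat b_{gy} \sim N(0, 1)} and forms the Wald ratios
#' \eqn{\hat b_{gy}/\hat b_{gx}}. Unselected, the ratio of normals is
#' fat-tailed (Cauchy-like when the instrument is weak); conditioning on
#' \eqn{\hat b_{gx}^2 \ge cutoff} compresses the denominator's range and
#' the selected ratios look approximately normal.
#'
#' @param b_gx True SNP-exposure effect (mean of the denominator normal).
#' @param cutoff Wald cutoff applied to `b_gx_hat^2`; `0` disables selection.
#' @param n_total Number of pairs, `>= 1`.
#' @param seed Optional RNG seed.
#' @return An object of class `"wald_ratio_sim"`: list with `unselected`
#'   (all ratios), `selected` (ratios with `b_gx_hat^2 >= cutoff`),
#'   `n_selected`, `b_gx_hat`, `b_gy_hat`, `b_gx`, `cutoff`, `seed`.
#' @examples
#' sim <- simulate_wald_ratio_selection(sqrt(13), 29.71679, 10000, seed = 1)
#' sim$n_selected
#' @export
simulate_wald_ratio_selection <- function(b_gx, cutoff, n_total, seed = NULL) {
  if (length(n_total) != 1L || !is.finite(n_total) || n_total < 1) stop("'n_total' must be >= 1")
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff < 0) stop("'cutoff' must be >= 0")
  n_total <- as.integer(n_total)
  with_seed(seed, {
    b_gx_hat <- stats::rnorm(n_total, mean = b_gx, sd = 1)
    b_gy_hat <- stats::rnorm(n_total, mean = 0, sd = 1)
    ratios <- b_gy_hat / b_gx_hat
    keep <- b_gx_hat^2 >= cutoff
    structure(
      list(unselected = ratios, selected = ratios[keep],
           n_selected = sum(keep), b_gx_hat = b_gx_hat, b_gy_hat = b_gy_hat,
           b_gx = b_gx, cutoff = cutoff, n_total = n_total, seed = seed),
      class = "wald_ratio_sim"
    )
  })
}

#' @export
print.wald_ratio_sim <- function(x, ...) {
  cat("Wald-ratio selection experiment\n")
  cat(sprintf("  b_gx = %g, cutoff = %g, pairs = %d, selected = %d\n",
              x$b_gx, x$cutoff, x$n_total, x$n_selected))
  cat(sprintf("  excess kurtosis: unselected %.2f, selected %.2f\n",
              excess_kurtosis(x$unselected),
              if (x$n_selected > 3) excess_kurtosis(x$selected) else NA_real_))
  invisible(x)
}

# Sample excess kurtosis (reference: 0 for a normal).
excess_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}

#' Fisher-Z selection experiment for the MR Steiger statistic
#'
#' Reproduces the two-sample selection experiments: `n_reps` independent
#' pairs \eqn{z_{gx} \sim N(z(\rho), 1/(n_x-3))},
#' \eqn{z_{gy} \sim N(z(\rho), 1/(n_y-3))} are drawn (all `z_gx` first,
#' then all `z_gy`), and only pairs with both coordinates at or above
#' their Fisher-Z selection cutoffs (derived from `p_threshold` via
#' [selection_design()]) are kept. The Steiger statistic is computed on
#' the kept pairs and its two-sided rejection proportion is reported at
#' each requested level — the type-I error under the equal-correlation
#' null, distorted by selection.
#'
#' @param rho Common true correlation of the SNP with exposure and
#'   outcome, `|rho| < 1`.
#' @param n_x,n_y Study sample sizes, `>= 4`.
#' @param p_threshold Selection p-value in (0, 1]; `1` disables selection.
#' @param n_reps Number of replicate pairs, `>= 1`.
#' @param alphas Numeric vector of two-sided levels for the type-I error
#'   summary.
#' @param seed Optional RNG seed.
#' @return An object of class `"steiger_selection_sim"`: list with
#'   `z_gx`, `z_gy` (selected columns), `n_selected`, `n_reps`, `t_stats`
#'   (Steiger statistics on selected pairs), `type1` (named rejection
#'   proportions), `mean_z_gx`, `mean_z_gy`, `c_gx`, `c_gy` (cutoffs),
#'   `rho`, `n_x`, `n_y`, `p_threshold`, `seed`.
#' @examples
#' sim <- simulate_steiger_selection(0.15, 1000, 10000, 5e-8,
#'                                   n_reps = 10000, seed = 1)
#' sim$n_selected; sim$type1
#' @export
simulate_steiger_selection <- function(rho, n_x, n_y, p_threshold = 5e-8,
                                       n_reps = 10000,
                                       alphas = c(0.05, 0.01), seed = NULL) {
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  if (n_x < 4 || n_y < 4) stop("sample sizes must be at least 4")
  if (length(n_reps) != 1L || !is.finite(n_reps) || n_reps < 1) stop("'n_reps' must be >= 1")
  n_reps <- as.integer(n_reps)
  cuts <- steiger_cutoffs(p_threshold, n_x, n_y)
  mu <- fisher_z(rho)
  with_seed(seed, {
    z_gx <- stats::rnorm(n_reps, mean = mu, sd = 1 / sqrt(n_x - 3))
    z_gy <- stats::rnorm(n_reps, mean = mu, sd = 1 / sqrt(n_y - 3))
    keep <- z_gx >= cuts$c_gx & z_gy >= cuts$c_gy
    zx <- z_gx[keep]; zy <- z_gy[keep]
    t_stats <- (zx - zy) / sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
    type1 <- vapply(alphas, function(a) type1_error_rate(t_stats, a), numeric(1))
    names(type1) <- as.character(alphas)
    structure(
      list(z_gx = zx, z_gy = zy, n_selected = length(zx), n_reps = n_reps,
           t_stats = t_stats, type1 = type1,
           mean_z_gx = if (length(zx)) mean(zx) else NA_real_,
           mean_z_gy = if (length(zy)) mean(zy) else NA_real_,
           c_gx = cuts$c_gx, c_gy = cuts$c_gy,
           rho = rho, n_x = n_x, n_y = n_y, p_threshold = p_threshold,
           seed = seed),
      class = "steiger_selection_sim"
    )
  })
}

# Fisher-Z cutoffs implied by a selection p-value at the two sample sizes;
# p_threshold = 1 means no selection (cutoff -Inf).
steiger_cutoffs <- function(p_threshold, n_x, n_y) {
  if (length(p_threshold) != 1L || !is.finite(p_threshold) ||
      p_threshold <= 0 || p_threshold > 1) {
    stop("'p_threshold' must lie in (0, 1]")
  }
  if (p_threshold == 1) return(list(c_gx = -Inf, c_gy = -Inf))
  d <- selection_design(p_threshold)
  list(c_gx = d$fisher_z_cutoff(n_x), c_gy = d$fisher_z_cutoff(n_y))
}

#' @export
print.steiger_selection_sim <- function(x, ...) {
  cat("Fisher-Z selection experiment (MR Steiger)\n")
  cat(sprintf("  rho = %g, n_x = %d, n_y = %d, p-threshold = %g\n",
              x$rho, as.integer(x$n_x), as.integer(x$n_y), x$p_threshold))
  cat(sprintf("  selected %d of %d replicates\n", x$n_selected, x$n_reps))
  cat(sprintf("  mean selected z_gx = %.7f, z_gy = %.7f (true z = %.7f)\n",
              x$mean_z_gx, x$mean_z_gy, fisher_z(x$rho)))
  for (a in names(x$type1)) {
    cat(sprintf("  type-I error at alpha = %s : %.8f\n", a, x$type1[[a]]))
  }
  invisible(x)
}

#' @export
plot.steiger_selection_sim <- function(x, ...) {
  stats::qqnorm(x$t_stats, main = sprintf(
    "T_Steiger under selection (rho = %g, n_x = %d, n_y = %d)",
    x$rho, as.integer(x$n_x), as.integer(x$n_y)), ...)
  stats::qqline(x$t_stats, lty = 2)
  invisible(x)
}

#' Analytic selection probability for the Fisher-Z experiment
#'
#' Closed-form probability that an independent pair passes both Fisher-Z
#' cutoffs: the product of two normal upper tails with means
#' \eqn{z(\rho)} and variances \eqn{1/(n-3)}. Serves as the oracle against
#' which simulated selection counts are bounded.
#'
#' @inheritParams simulate_steiger_selection
#' @return Probability in \code{[0, 1]}; `1` when `p_threshold = 1`.
#' @examples
#' steiger_selection_probability(0.15, 1000, 10000, 5e-8)  # ~ 0.258
#' @export
steiger_selection_probability <- function(rho, n_x, n_y, p_threshold = 5e-8) {
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")
  if (n_x < 4 || n_y < 4) stop("sample sizes must be at least 4")
  cuts <- steiger_cutoffs(p_threshold, n_x, n_y)
  if (p_threshold == 1) return(1)
  mu <- fisher_z(rho)
  stats::pnorm(cuts$c_gx, mean = mu, sd = 1 / sqrt(n_x - 3), lower.tail = FALSE) *
    stats::pnorm(cuts$c_gy, mean = mu, sd = 1 / sqrt(n_y - 3), lower.tail = FALSE)
}

#' Two-sided rejection proportion of a statistic sample
#'
#' Fraction of statistics whose two-sided p-value falls below `alpha`
#' under the stated reference distribution: standard normal for Steiger
#' statistics, 1-df chi-square for Wald-type statistics.
#'
#' @param t_stats Nonempty numeric vector of statistics.
#' @param alpha Level in (0, 1).
#' @param reference `"normal"` (two-sided on \eqn{|t|}) or `"chisq1"`
#'   (upper tail, statistics already on the chi-square scale).
#' @return Proportion rejected, in \code{[0, 1]}.
#' @examples
#' type1_error_rate(rnorm(1000), 0.05)
#' @export
type1_error_rate <- function(t_stats, alpha, reference = c("normal", "chisq1")) {
  if (length(t_stats) == 0L) stop("'t_stats' must be nonempty")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  reference <- match.arg(reference)
  p <- switch(reference,
    normal = 2 * stats::pnorm(abs(t_stats), lower.tail = FALSE),
    chisq1 = chisq_upper_p(t_stats)
  )
  mean(p < alpha)
}

#' Paired quantiles for a quantile-quantile plot
#'
#' Matches the sorted sample against either the equally-sized sorted
#' reference sample or the theoretical quantiles of a named distribution
#' at the plotting positions `ppoints(n)`.
#'
#' @param sample Nonempty numeric vector.
#' @param reference Either a numeric vector (an empirical reference
#'   sample; quantiles at `ppoints(length(sample))` are used when lengths
#'   differ) or one of `"chisq1"`, `"normal"`.
#' @return A `data.frame` with columns `reference` and `sample`, both
#'   sorted, suitable for plotting; monotone in both coordinates.
#' @examples
#' qq_points(rchisq(100, 1), "chisq1")
#' @export
qq_points <- function(sample, reference = "chisq1") {
  if (length(sample) == 0L) stop("'sample' must be nonempty")
  n <- length(sample)
  ref <- if (is.character(reference)) {
    switch(match.arg(reference, c("chisq1", "normal")),
      chisq1 = stats::qchisq(stats::ppoints(n), df = 1),
      normal = stats::qnorm(stats::ppoints(n))
    )
  } else if (length(reference) == n) {
    sort(reference)
  } else {
    stats::quantile(reference, probs = stats::ppoints(n), names = FALSE, type = 7)
  }
  data.frame(reference = ref, sample = sort(sample))
}
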