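test_that("chi-square selection respects floor, count oracle, and seed", {
  w <- p_to_chisq_threshold(5e-8)
  sim <- simulate_chisq_selection(13, w, 10000, seed = 7)
  expect_true(all(sim$selected >= w))
  expect_equal(sim$n_selected, length(sim$selected))
  p_star <- chisq_selection_prob_oracle(13, w)
  expect_equal(p_star, 0.0325, tolerance = 0.01)
  expect_lt(abs(sim$n_selected - 10000 * p_star),
            4 * sqrt(10000 * p_star * (1 - p_star)))
  # null calibration: essentially nothing survives the genome-wide cutoff
  expect_lte(simulate_chisq_selection(0, w, 10000, seed = 8)$n_selected, 1)
  # determinism and stream restoration
  again <- simulate_chisq_selection(13, w, 10000, seed = 7)
  expect_identical(sim$draws, again$draws)
  expect_error(simulate_chisq_selection(-1, w, 100), "ncp")
  expect_error(simulate_chisq_selection(1, w, 0), "n_total")
})

test_that("selection normalizes the fat-tailed Wald-ratio distribution", {
  w <- p_to_chisq_threshold(5e-8)
  sim <- simulate_wald_ratio_selection(sqrt(13), w, 10000, seed = 21)
  # unselected ratio of normals: strongly fat-tailed
  expect_gt(kurtosis_oracle(sim$unselected), 3)
  # selected subsample: compatible with a normal
  expect_gt(sim$n_selected, 200)
  expect_lt(abs(kurtosis_oracle(sim$selected)), 1)
  expect_gt(shapiro.test(sim$selected)$p.value, 0.01)
  # cutoff zero disables selection
  all_in <- simulate_wald_ratio_selection(sqrt(13), 0, 500, seed = 3)
  expect_identical(all_in$selected, all_in$unselected)
})

test_that("Fisher-Z selection experiment matches its analytic oracles", {
  sim <- simulate_steiger_selection(0.15, 1000, 10000, 5e-8,
                                    n_reps = 10000, seed = 19)
  expect_equal(length(sim$z_gx), sim$n_selected)
  expect_equal(length(sim$t_stats), sim$n_selected)
  expect_true(all(sim$z_gx >= sim$c_gx))
  expect_true(all(sim$z_gy >= sim$c_gy))
  expect_true(all(sim$type1 >= 0 & sim$type1 <= 1))

  # count concentration around the closed-form selection probability
  p_sel <- steiger_selection_prob_oracle(0.15, 1000, 10000)
  expect_equal(steiger_selection_probability(0.15, 1000, 10000), p_sel,
               tolerance = 1e-12)
  expect_lt(abs(sim$n_selected - 10000 * p_sel),
            4 * sqrt(10000 * p_sel * (1 - p_sel)))

  # winner's curse: upward bias and variance shrinkage of the selected column
  expect_gt(sim$mean_z_gx, fisher_z(0.15))
  expect_lt(var(sim$z_gx), 1 / 997)
  mu_trunc <- truncnorm_mean_oracle(fisher_z(0.15), 1 / sqrt(997), sim$c_gx)
  expect_lt(abs(sim$mean_z_gx - mu_trunc),
            4 * sd(sim$z_gx) / sqrt(sim$n_selected))

  expect_identical(
    simulate_steiger_selection(0.15, 1000, 10000, 5e-8, 10000, seed = 19)$t_stats,
    sim$t_stats)
})

test_that("without selection the Steiger test is calibrated; symmetric designs stay conservative", {
  free <- simulate_steiger_selection(0.2, 1000, 5000, p_threshold = 1,
                                     n_reps = 10000, seed = 5)
  expect_equal(free$n_selected, 10000)
  for (a in c(0.05, 0.01)) {
    expect_lt(abs(free$type1[[as.character(a)]] - a), mc_tol_prop(a, 10000))
  }
  # equal sample sizes: selection truncates both z's identically, the
  # numerator stays centred and the test cannot be liberal
  sym <- simulate_steiger_selection(0.15, 2000, 2000, 5e-8,
                                    n_reps = 10000, seed = 6)
  expect_gt(sym$n_selected, 100)
  expect_lte(sym$type1[["0.05"]], 0.05 + mc_tol_prop(0.05, sym$n_selected))
})

test_that("type1_error_rate counts two-sided rejections under both references", {
  expect_equal(type1_error_rate(rep(0, 10), 0.05), 0)
  set.seed(31)
  z <- rnorm(20000)
  expect_lt(abs(type1_error_rate(z, 0.05) - 0.05), mc_tol_prop(0.05, 20000))
  expect_lt(abs(type1_error_rate(z^2, 0.05, reference = "chisq1") - 0.05),
            mc_tol_prop(0.05, 20000))
  expect_equal(type1_error_rate(c(0, qnorm(0.999)), 0.05), 0.5)
  expect_error(type1_error_rate(numeric(0), 0.05), "nonempty")
  expect_error(type1_error_rate(1, 0), "alpha")
})

test_that("qq_points pairs sorted quantiles monotonically", {
  s <- c(3, 1, 2)
  qq <- qq_points(s, reference = s)
  expect_equal(qq$reference, qq$sample)          # 45-degree line
  expect_equal(qq$sample, sort(s))
  qq2 <- qq_points(rep(2, 5), "normal")          # constant sample
  expect_true(all(qq2$sample == 2))
  expect_true(all(diff(qq2$reference) > 0))
  set.seed(41)
  qq3 <- qq_points(rchisq(100, 1), rchisq(250, 1))
  expect_equal(nrow(qq3), 100)
  expect_true(all(diff(qq3$reference) >= 0) && all(diff(qq3$sample) >= 0))
  expect_error(qq_points(numeric(0)), "nonempty")
})

test_that("selection lifts the low quantiles of the Wald distribution", {
  w <- p_to_chisq_threshold(5e-8)
  sim <- simulate_chisq_selection(13, w, 10000, seed = 9)
  # selected order statistics sit above the unselected reference at the
  # low end: the selection floor cuts the left tail
  low <- seq_len(ceiling(sim$n_selected / 4))
  expect_true(all(sim$qq_pairs$sample[low] >= w))
  expect_gt(mean(sim$qq_pairs$sample[low] - sim$qq_pairs$reference[low]), 0)
})
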