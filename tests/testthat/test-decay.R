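test_that("noiseless data recover the generating curve to 1%", {
  fit <- fit_decay(noiseless_series(), short_mcmc(1))
  expect_lt(abs(fit$k$value - 2) / 2, 0.01)
  expect_lt(abs(fit$r_offset$value - 1), 0.01)
  expect_lt(abs(fit$c0$value - 11) / 11, 0.01)
})

test_that("every retained draw honours the positivity constraints", {
  fit <- fit_decay(noiseless_series(), short_mcmc(2))
  expect_true(all(fit$draws[, "k"] >= 0))
  expect_true(all(fit$draws[, "c_deg"] >= 0))
  expect_true(all(fit$draws[, "r_offset"] >= 0))
  fr <- recalcitrant_fraction(fit)
  expect_true(fr$value >= 0 && fr$value <= 1)
  # fitted curve at the posterior mean is monotone non-increasing
  tt <- seq(0, 5, by = 0.1)
  curve <- fit$c_deg$value * exp(-fit$k$value * tt) + fit$r_offset$value
  expect_true(all(diff(curve) <= 0))
})

test_that("recalcitrant fraction is invariant under rescaling the loadings", {
  t <- c(0, 0.4, 0.9, 1.5, 2.2, 3.1)
  y <- 5 * exp(-2.4 * t) + 0.7
  base <- pool_series("p", t, rep(0.05, 6), y, 0.08 * y)
  scaled <- pool_series("p", t, rep(0.05, 6), 1000 * y, 0.08 * 1000 * y)
  f1 <- fit_decay(base, short_mcmc(5))
  f2 <- fit_decay(scaled, short_mcmc(5))
  # same seed + scale-equivariant sampler: identical f_R and k chains
  expect_equal(f1$f_r$value, f2$f_r$value, tolerance = 1e-10)
  expect_equal(f1$k$value, f2$k$value, tolerance = 1e-10)
  expect_equal(f2$c0$value / f1$c0$value, 1000, tolerance = 1e-10)
})

test_that("remaining fraction interpolates between 1 and f_R", {
  expect_equal(remaining_fraction(2.4, 0, f_r = 0.13), 1)
  expect_equal(remaining_fraction(2.4, 1e6, f_r = 0.13), 0.13)
  # at the shelf-edge transport time the loss is ~87%
  rem <- remaining_fraction(2.4, 3.56, f_r = 0.13)
  expect_equal(rem, 0.13 + 0.87 * exp(-2.4 * 3.56), tolerance = 1e-12)
  expect_gt(1 - rem, 0.82)
  expect_lt(1 - rem, 0.90)
  fit <- fit_decay(noiseless_series(), short_mcmc(3))
  r <- remaining_fraction(fit, 1.0)
  expect_true(r$value > fit$f_r$value && r$value < 1)
  expect_equal(remaining_fraction(fit, 0)$value, 1, tolerance = 1e-12)
  expect_error(remaining_fraction(fit, -1), "non-negative")
})

test_that("posterior-mean k is repeatable across chains to <1% RSD", {
  cfg <- synthetic_config(seed = 99)
  tr <- generate_transect(cfg)
  ps <- pool_series("terrOC", tr$truth$tau_kyr,
                    0.09 * tr$truth$tau_kyr,
                    tr$stations$loading_terrOC,
                    tr$stations$loading_terrOC_sd)
  ks <- vapply(1:10, function(s) {
    fit_decay(ps, mcmc_config(1e5, 1e4, 10, seed = 7000 + s))$k$value
  }, numeric(1))
  expect_lt(sd(ks) / mean(ks) * 100, 1)
})

test_that("inner-shelf subsetting returns a consistent comparison record", {
  # constant-k truth: the subset rate agrees with the full-transect rate
  t <- seq(0.1, 3.5, length.out = 12)
  set.seed(42)
  y <- (0.13 + 0.87 * exp(-2.4 * t)) * exp(rnorm(12, 0, 0.05))
  ps <- pool_series("terrOC", t, rep(0.05, 12), y, 0.05 * y)
  cmp <- compare_subset(ps, t_max_kyr = 1.5, mcmc = mcmc_config(1e5, 1e4,
                                                                10,
                                                                seed = 21))
  expect_equal(cmp$n_full, 12)
  expect_gte(cmp$n_subset, 4)
  sig <- sqrt(cmp$k_full$sigma^2 + cmp$k_subset$sigma^2)
  expect_lt(abs(cmp$k_subset$value - cmp$k_full$value), 2.5 * sig)
  # the short-baseline subset is the less certain estimate
  expect_gt(cmp$rel_sd_subset, cmp$rel_sd_full)
  expect_error(compare_subset(ps, t_max_kyr = 0.2,
                              mcmc = mcmc_config(seed = 1)),
               "fewer than 4")
})

test_that("series validation enforces the model's preconditions", {
  expect_error(pool_series("p", c(0, 1, 2), rep(0, 3), c(1, 1, 1),
                           rep(0.1, 3)), "at least 4")
  expect_error(pool_series("p", c(0, 1, 2, -1), rep(0, 4), rep(1, 4),
                           rep(0.1, 4)), "non-negative")
  expect_error(pool_series("p", c(0, 1, 2, 3), rep(0, 4), rep(1, 4),
                           rep(0, 4)), "positive")
  expect_error(fit_decay(noiseless_series(), mcmc_config(1e4, 1e3, 1)),
               "seed")
})
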