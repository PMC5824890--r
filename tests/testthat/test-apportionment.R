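test_that("the active-layer endmember decays with transport time", {
  e0 <- build_endmembers(tau_kyr = 0, sampling_year = 2010)
  expect_equal(e0$d14c[1], -232)
  expect_equal(e0$d14c_sd[1], 147)
  e39 <- build_endmembers(tau_kyr = 3.9, sampling_year = 2010)
  # closed form: ((1 - 0.232) e^{-3900/8033} - 1) * 1000
  expect_equal(e39$d14c[1], ((1 - 0.232) * exp(-3900 / 8033) - 1) * 1000,
               tolerance = 1e-9)
  expect_equal(e39$d14c[1], -527.4, tolerance = 0.05)
  expect_equal(e39$d14c_sd[1], 147 * exp(-3900 / 8033), tolerance = 1e-9)
  expect_equal(e39$d14c_sd[1], 90.5, tolerance = 0.05)
  # time-independent endmembers pass through
  expect_equal(e39$d14c[2], -940)
  expect_equal(e39$d14c[3], -50)
  expect_equal(e39$d13c, e0$d13c)
  # the sampling-year factor cancels in the decay round trip
  e39b <- build_endmembers(tau_kyr = 3.9, sampling_year = 1950)
  expect_equal(e39$d14c[1], e39b$d14c[1], tolerance = 1e-9)
  expect_error(build_endmembers(tau_kyr = -1), "non-negative")
})

test_that("a pure-endmember sample is attributed to its source", {
  ems <- default_endmembers()
  ems$d13c_sd <- ems$d13c_sd / 100
  ems$d14c_sd <- ems$d14c_sd / 100
  obs <- isotope_observation(-21.0, 0.025, -50, 0.12, 1950)
  mix <- apportion_sample(obs, ems, mid_mcmc(5))
  expect_gt(mix$fractions$mean[3], 0.95)
})

test_that("posterior fractions match the exact grid posterior", {
  samples <- list(
    list(obs = mid_triangle_obs(), tau = 1.0),
    list(obs = isotope_observation(-26.0, 0.2, -700, 5, 2010), tau = 0.3),
    list(obs = isotope_observation(-22.5, 0.2, -200, 5, 2010), tau = 3.0))
  for (s in samples) {
    ems <- build_endmembers(tau_kyr = s$tau, sampling_year = 2010)
    mix <- apportion_sample(s$obs, ems, mid_mcmc(31))
    grid <- grid_posterior_fractions(s$obs, ems)
    want <- attr(grid, "means")
    expect_lt(max(abs(mix$fractions$mean - want)), 0.02)
  }
})

test_that("every retained draw lies on the simplex and closes f_terr", {
  mix <- apportion_sample(mid_triangle_obs(),
                          build_endmembers(tau_kyr = 1,
                                           sampling_year = 2010),
                          mid_mcmc(8))
  expect_true(all(mix$draws >= 0))
  expect_true(all(abs(rowSums(mix$draws) - 1) < 1e-12))
  terr <- mix$draws[, "f_AL"] + mix$draws[, "f_ICD"]
  expect_true(all(abs(terr - (1 - mix$draws[, "f_marine"])) < 1e-12))
  expect_equal(fraction_terroc(mix)$value, mean(terr))
})

test_that("burn-in and thinning yield the configured retained-draw count", {
  mc <- mcmc_config(40000, 4000, 9, seed = 2)
  mix <- apportion_sample(mid_triangle_obs(),
                          build_endmembers(tau_kyr = 1,
                                           sampling_year = 2010), mc)
  expect_equal(mix$n_retained, (40000 - 4000) %/% 9)
})

test_that("realized acceptance lands near the tuning target", {
  for (seed in c(3, 14)) {
    mix <- apportion_sample(mid_triangle_obs(),
                            build_endmembers(tau_kyr = 1,
                                             sampling_year = 2010),
                            mid_mcmc(seed))
    expect_gt(mix$acceptance_rate, 0.18)
    expect_lt(mix$acceptance_rate, 0.28)
  }
})

test_that("the posterior is invariant to relabeling ICD and marine", {
  obs <- mid_triangle_obs()
  ems <- build_endmembers(tau_kyr = 1, sampling_year = 2010)
  swapped <- ems[c(1, 3, 2), ]
  attr(swapped, "tau_kyr") <- attr(ems, "tau_kyr")
  attr(swapped, "sampling_year") <- attr(ems, "sampling_year")
  class(swapped) <- class(ems)
  a <- apportion_sample(obs, ems, mid_mcmc(12))
  b <- apportion_sample(obs, swapped, mid_mcmc(12))
  expect_lt(abs(a$fractions$mean[2] - b$fractions$mean[3]), 0.015)
  expect_lt(abs(a$fractions$mean[3] - b$fractions$mean[2]), 0.015)
  expect_lt(abs(a$fractions$mean[1] - b$fractions$mean[1]), 0.015)
})

test_that("widening an endmember prior never sharpens its fraction", {
  obs <- mid_triangle_obs()
  ems <- build_endmembers(tau_kyr = 1, sampling_year = 2010)
  wide <- ems
  wide$d13c_sd[1] <- wide$d13c_sd[1] * 2
  wide$d14c_sd[1] <- wide$d14c_sd[1] * 2
  sd_of <- function(e) {
    g <- grid_posterior_fractions(obs, e)
    m <- attr(g, "means")[1]
    sqrt(sum(g$prob * (g$f_AL - m)^2))
  }
  expect_gte(sd_of(wide), sd_of(ems))
})

test_that("f_terr is better constrained than its two components", {
  # AL and ICD have nearly equal d13C, so their split is soft while the
  # terrestrial total is pinned by Delta-14C; clearest for a sample whose
  # Delta-14C lies between the two permafrost endmembers
  obs <- isotope_observation(-25, 0.2, -600, 5, 2010)
  mix <- apportion_sample(obs,
                          build_endmembers(tau_kyr = 1,
                                           sampling_year = 2010),
                          mid_mcmc(9))
  expect_lt(mix$f_terr$sigma, mix$fractions$sd[1])
  expect_lt(mix$f_terr$sigma, mix$fractions$sd[2])
})

test_that("chains are deterministic given a seed and repeatable across seeds", {
  obs <- mid_triangle_obs()
  ems <- build_endmembers(tau_kyr = 1, sampling_year = 2010)
  a <- apportion_sample(obs, ems, mid_mcmc(77))
  b <- apportion_sample(obs, ems, mid_mcmc(77))
  expect_identical(a$draws, b$draws)
  # shorter chains are less repeatable than longer ones
  rsd_at <- function(n_iter, burn) {
    m <- vapply(1:6, function(s) {
      apportion_sample(obs, ems,
                       mcmc_config(n_iter, burn, 10,
                                   seed = 500 + s))$f_terr$value
    }, numeric(1))
    sd(m) / mean(m)
  }
  expect_gt(rsd_at(2e4, 2e3), rsd_at(4e5, 1e4))
})
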