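test_that("exact collinear points are interpolated perfectly", {
  m <- fit_age_depth(c(0, 50, 100), c(6, 8, 10), c(0, 0, 0),
                     n_draws = 1000, seed = 1)
  expect_equal(m$a$value, 0.040, tolerance = 1e-12)
  expect_equal(m$b$value, 6.0, tolerance = 1e-12)
  expect_equal(m$a$sigma, 0, tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
})

test_that("input validation catches degenerate designs", {
  expect_error(fit_age_depth(c(1, 2), c(1, 2), c(0.1, 0.1), seed = 1),
               "at least 3")
  expect_error(fit_age_depth(c(5, 5, 5), c(1, 2, 3), rep(0.1, 3), seed = 1),
               "rank-deficient")
  expect_error(fit_age_depth(c(1, 2, 3), c(1, 2, 3), rep(0.1, 3)),
               "seed")
})

test_that("Monte-Carlo slope is unbiased relative to the unperturbed OLS fit", {
  st <- dated_stations()
  m <- fit_age_depth(st$depth_m, st$csra_cal_age_kyr,
                     st$csra_cal_age_sd_kyr, n_draws = 10000, seed = 11)
  ols <- coef(lm(st$csra_cal_age_kyr ~ st$depth_m))
  mc_se <- m$a$sigma / sqrt(m$n_draws)
  expect_lt(abs(m$a$value - ols[2]), 3 * mc_se)
  mc_se_b <- m$b$sigma / sqrt(m$n_draws)
  expect_lt(abs(m$b$value - ols[1]), 3 * mc_se_b)
})

test_that("transport time is homogeneous of degree 1 in depth", {
  st <- dated_stations()
  m <- fit_age_depth(st$depth_m, st$csra_cal_age_kyr,
                     st$csra_cal_age_sd_kyr, n_draws = 2000, seed = 7)
  t1 <- transport_time_at_depth(m, 40)
  t2 <- transport_time_at_depth(m, 80)
  expect_equal(t2$value, 2 * t1$value, tolerance = 1e-12)
  expect_equal(t2$sigma, 2 * t1$sigma, tolerance = 1e-12)
  expect_equal(transport_time_at_depth(m, 0)$value, 0)
  expect_error(transport_time_at_depth(m, -5), "non-negative")
})

test_that("transport time from age subtracts the intercept in quadrature", {
  st <- dated_stations()
  m <- fit_age_depth(st$depth_m, st$csra_cal_age_kyr,
                     st$csra_cal_age_sd_kyr, n_draws = 5000, seed = 7)
  tau <- transport_time_from_age(qty(9.99, 0.34), m)
  expect_equal(tau$value, 9.99 - mean(m$b_draws), tolerance = 1e-12)
  expect_equal(tau$sigma, sqrt(0.34^2 + var(m$b_draws)), tolerance = 1e-12)
  # river-mouth boundary case: age younger than the intercept
  expect_warning(transport_time_from_age(qty(6.30, 0.16), m), "negative")
})

test_that("generator truth is recovered across seeded repetitions", {
  hits <- 0
  n_rep <- 25
  for (s in seq_len(n_rep)) {
    cfg <- synthetic_config(n_stations = 8, seed = 400 + s)
    tr <- generate_transect(cfg)
    st <- tr$stations
    ok <- !is.na(st$csra_cal_age_kyr)
    m <- fit_age_depth(st$depth_m[ok], st$csra_cal_age_kyr[ok],
                       st$csra_cal_age_sd_kyr[ok], n_draws = 2000,
                       seed = s)
    if (abs(m$a$value - 0.039) < 2 * m$a$sigma &&
        abs(m$b$value - 6.6) < 2 * m$b$sigma) hits <- hits + 1
  }
  expect_gte(hits, round(0.8 * n_rep))
})

test_that("inverse-variance weighting is available and changes the estimate", {
  st <- dated_stations()
  mu <- fit_age_depth(st$depth_m, st$csra_cal_age_kyr,
                      st$csra_cal_age_sd_kyr, n_draws = 2000, seed = 3)
  mw <- fit_age_depth(st$depth_m, st$csra_cal_age_kyr,
                      st$csra_cal_age_sd_kyr, n_draws = 2000, seed = 3,
                      weights = "inverse_variance")
  expect_false(isTRUE(all.equal(mu$a$value, mw$a$value)))
  s <- transport_model_summary(mw)
  expect_identical(s$weights, "inverse_variance")
  expect_identical(s$seed, 3)
})
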