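test_that("Delta-14C to fraction-modern conversion matches its definition", {
  expect_equal(delta14c_to_fm(qty(0, 0), 1950)$value, 1.0)
  expect_equal(delta14c_to_fm(qty(-1000, 0), 2014)$value, 0.0)
  # closed-form spot check away from the reference year
  fm <- delta14c_to_fm(qty(-364, 2), 2014)
  expect_equal(fm$value, (1 - 0.364) * exp(64 / 8033), tolerance = 1e-12)
  expect_equal(fm$value, 0.6411, tolerance = 1e-4)
  expect_equal(fm$sigma, 2 / 1000 * exp(64 / 8033), tolerance = 1e-12)
  expect_error(delta14c_to_fm(qty(-1000.5, 0)), "physical")
  expect_error(delta14c_to_fm(qty(0, 0), 1900), "reference year")
})

test_that("fm <-> Delta-14C round trip is the identity", {
  expect_equal(fm_to_delta14c(qty(1, 0), 1950)$value, 0)
  expect_equal(fm_to_delta14c(qty(0, 0), 2008)$value, -1000)
  for (d in c(-999, -415, -232, -50, 0, 150)) {
    for (yr in c(1950, 2008, 2014)) {
      back <- fm_to_delta14c(delta14c_to_fm(qty(d, 3), yr), yr)
      expect_equal(back$value, d, tolerance = 1e-12)
      expect_equal(back$sigma, 3, tolerance = 1e-12)
    }
  }
  expect_error(fm_to_delta14c(qty(-1, 0)), "non-negative")
})

test_that("conventional ages reproduce the published bulk-age column", {
  expect_equal(conventional_age(qty(1, 0))$value, 0)
  st <- laptev_stations()
  has <- !is.na(st$d14c_toc)
  for (i in which(has)) {
    age <- conventional_age(delta14c_to_fm(
      qty(st$d14c_toc[i], st$d14c_toc_sd[i]), st$sampling_year[i]))
    expect_lt(abs(age$value - st$c14_age_toc_kyr[i]), 0.02)
  }
  expect_error(conventional_age(qty(0, 0)), "infinite")
})

test_that("signature decay is exponential in tau and preserves relative sigma", {
  f <- qty(0.768, 0.147)
  expect_identical(decay_signature(f, 0), f)
  # one mean life from the 1950 atmosphere: (e^-1 - 1) * 1000 per mil
  d <- fm_to_delta14c(decay_signature(delta14c_to_fm(qty(0, 0), 1950), 8033),
                      1950)
  expect_equal(d$value, (exp(-1) - 1) * 1000, tolerance = 1e-9)
  # monotone decrease in both moments, constant sigma/mean ratio
  taus <- seq(0, 10000, by = 500)
  vals <- vapply(taus, function(t) decay_signature(f, t)$value, 1)
  sigs <- vapply(taus, function(t) decay_signature(f, t)$sigma, 1)
  expect_true(all(diff(vals) < 0))
  expect_true(all(diff(sigs) < 0))
  expect_equal(sigs / vals, rep(f$sigma / f$value, length(taus)),
               tolerance = 1e-12)
  expect_error(decay_signature(f, -1), "non-negative")
})

test_that("age additivity: decay by tau adds tau to the conventional age", {
  f <- qty(0.7, 0.01)
  for (tau in c(0, 100, 3900, 8033)) {
    expect_equal(conventional_age(decay_signature(f, tau))$value,
                 conventional_age(f)$value + tau / 1000,
                 tolerance = 1e-12)
  }
})

test_that("methylation correction follows isotope mass balance", {
  expect_equal(methylation_correct(qty(0.48, 0), 24)$value, 0.50,
               tolerance = 1e-12)
  # isotopically identical methyl leaves the signature unchanged
  f <- qty(0.63, 0.01)
  expect_equal(methylation_correct(f, 26, f)$value, f$value,
               tolerance = 1e-12)
  # infinite-chain limit
  expect_equal(methylation_correct(qty(0.48, 0), 1e9)$value, 0.48,
               tolerance = 1e-8)
  expect_error(methylation_correct(qty(0.001, 0), 2, qty(0.9, 0)),
               "inconsistent")
  expect_error(methylation_correct(qty(0.5, 0), 0.5), "at least 1")
})

test_that("calibration reproduces identity and linear curves exactly", {
  id <- calibrate(qty(5.0, 0.05), identity_curve())
  expect_equal(id$point$value, 5.0, tolerance = 1e-3)
  expect_equal(id$point$sigma, 0.05, tolerance = 1e-3)
  lin <- calibrate(qty(5.0, 0.05), linear_curve(0.5))
  expect_equal(lin$point$value, 10.0, tolerance = 1e-3)
  expect_equal(lin$point$sigma, 0.10, tolerance = 1e-3)
  expect_equal(sum(id$pdf$prob), 1, tolerance = 1e-9)
})

test_that("calibration agrees with the dense-grid trapezoid oracle", {
  curve <- synthetic_curve()
  for (age in list(qty(3.0, 0.10), qty(5.5, 0.25), qty(9.0, 0.05))) {
    got <- calibrate(age, curve)
    want <- calibrate_oracle(age, curve)
    expect_lt(abs(got$point$value - want$mean_kyr) / want$mean_kyr, 1e-3)
    expect_lt(abs(got$point$sigma - want$sd_kyr) / want$sd_kyr, 0.02)
    expect_true(got$point$value >= got$hdi95[1] / 1000 - 1 &&
                  got$point$value <= got$hdi95[2] / 1000 + 1)
  }
})

test_that("calibration rejects ages outside curve coverage", {
  expect_error(calibrate(qty(50, 0.1), synthetic_curve()), "coverage")
})

test_that("calibration-curve files parse with comments and either delimiter", {
  curve <- synthetic_curve()
  expect_s3_class(curve, "cal_curve")
  expect_true(all(diff(curve$cal_bp) > 0))
  # whitespace-separated dialect
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# synthetic two-liner", "0 10 5", "100 110 5", "200 220 5"), p)
  ws <- read_calibration_curve(p)
  expect_equal(nrow(ws), 3)
  expect_equal(ws$c14_bp, c(10, 110, 220))
  # malformed row names its position
  writeLines(c("0,10,5", "badrow"), p)
  expect_error(read_calibration_curve(p), "line 2")
  writeLines(character(), p)
  expect_error(read_calibration_curve(p), "empty")
})
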