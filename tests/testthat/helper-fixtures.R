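# Shared fixture builders (all generated in code; no binary data).

# the eight transect stations with compound-specific ages
dated_stations <- function() {
  st <- laptev_stations()
  st[!is.na(st$csra_cal_age_kyr), ]
}

identity_curve <- function(step = 10, to = 12000) {
  cal <- seq(0, to, by = step)
  calibration_curve(cal, cal, rep(0, length(cal)))
}

linear_curve <- function(slope = 0.5, step = 10, to = 24000) {
  cal <- seq(0, to, by = step)
  calibration_curve(cal, slope * cal, rep(0, length(cal)))
}

synthetic_curve <- function() {
  read_calibration_curve(system.file("extdata", "synthetic_calcurve.txt",
                                     package = "shelfcarbon"))
}

# brute-force calibration oracle: 10x denser grid, trapezoid normalization
calibrate_oracle <- function(conv_age, curve, dense_factor = 10) {
  age_yr <- conv_age$value * 1000
  sig_yr <- conv_age$sigma * 1000
  step <- min(diff(curve$cal_bp)) / dense_factor
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = step)
  mu <- approx(curve$cal_bp, curve$c14_bp, xout = grid)$y
  sc <- approx(curve$cal_bp, curve$sigma, xout = grid)$y
  d <- dnorm(age_yr, mu, sqrt(sig_yr^2 + sc^2))
  w <- d
  w[1] <- w[1] / 2
  w[length(w)] <- w[length(w)] / 2  # trapezoid rule on a uniform grid
  w <- w / sum(w)
  m <- sum(w * grid)
  list(mean_kyr = m / 1000,
       sd_kyr = sqrt(sum(w * (grid - m)^2)) / 1000)
}

# a mid-triangle bulk-OC sample used across apportionment tests
mid_triangle_obs <- function() {
  isotope_observation(-24.5, 0.2, -400, 5, sampling_year = 2010)
}

# noiseless decay fixture on C(t) = 10 exp(-2 t) + 1
noiseless_series <- function() {
  t <- c(0, 0.5, 1, 1.5, 2, 3)
  pool_series("noiseless", t, rep(0, 6), 10 * exp(-2 * t) + 1,
              rep(1e-3, 6))
}

# quick protocols so unit tests stay fast; acceptance tests use the
# full-length protocol where the criterion depends on chain length
short_mcmc <- function(seed) mcmc_config(5e4, 5e3, 5, seed = seed)
mid_mcmc <- function(seed) mcmc_config(2e5, 1e4, 10, seed = seed)
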