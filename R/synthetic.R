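#' Configuration for a synthetic shelf transect
#'
#' Defines the generative model the analysis assumes, with known truth:
#' biomarker ages linear in depth with Gaussian noise, pool loadings on
#' the first-order-decay-with-offset curve with multiplicative lognormal
#' noise, and bulk dual-isotope values as three-endmember mixture means
#' (with the active-layer endmember decayed by each station's true
#' transport time) plus Gaussian measurement noise.
#'
#' Defaults mirror the Laptev Sea study conditions: 10 stations spanning
#' 4-92 m, inverse transport velocity a = 0.039 kyr/m, on-land pre-ageing
#' b = 6.6 kyr, age noise 0.2 kyr, a terrOC pool with k = 2.4 kyr^-1 and
#' f_R = 0.13 under 10% multiplicative loading noise, and the default
#' endmember priors. The fraction trajectory defaults to a marine share
#' growing linearly offshore with the terrestrial remainder split 60/40
#' between active-layer and Ice Complex permafrost.
#'
#' @param n_stations Number of stations (default 10).
#' @param depth_range Depth span in meters (default `c(4, 92)`).
#' @param a_kyr_per_m,b_kyr True age-depth line (defaults 0.039, 6.6).
#' @param age_sigma_kyr Gaussian age noise / reported age sigma (0.2).
#' @param pools Named list of pool truths, each
#'   `list(c0 = , k = , f_r = )`.
#' @param loading_sdlog Lognormal sdlog of the multiplicative loading
#'   noise (default 0.1, i.e. ~10%).
#' @param fraction_fun Function `depth_m -> c(f_AL, f_ICD, f_marine)` on
#'   the simplex.
#' @param endmembers No-transport endmember priors
#'   ([default_endmembers()]).
#' @param d13c_sigma,d14c_sigma Bulk isotope measurement noise /
#'   reported sigmas (per mil; defaults 0.2 and 5).
#' @param sampling_year Calendar year AD (default 2014).
#' @param csra_missing Integer indices of stations whose synthetic table
#'   omits the compound-specific age (exercises the depth-derived
#'   transport-time path); default `c(4, 8)`.
#' @param seed Integer seed; mandatory.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_stations = 10, depth_range = c(4, 92),
                             a_kyr_per_m = 0.039, b_kyr = 6.6,
                             age_sigma_kyr = 0.2,
                             pools = list(terrOC = list(c0 = 1, k = 2.4,
                                                        f_r = 0.13)),
                             loading_sdlog = 0.1,
                             fraction_fun = NULL,
                             endmembers = default_endmembers(),
                             d13c_sigma = 0.2, d14c_sigma = 5,
                             sampling_year = 2014,
                             csra_missing = c(4, 8),
                             seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_stations >= 3, depth_range[1] > 0,
            depth_range[2] > depth_range[1], age_sigma_kyr >= 0,
            loading_sdlog >= 0)
  for (p in pools) {
    stopifnot(p$k >= 0, p$f_r >= 0, p$f_r < 1, p$c0 > 0)
  }
  if (is.null(fraction_fun)) {
    fraction_fun <- function(depth_m) {
      fm <- 0.15 + 0.5 * depth_m / 92
      c(0.6 * (1 - fm), 0.4 * (1 - fm), fm)
    }
  }
  structure(list(n_stations = n_stations, depth_range = depth_range,
                 a_kyr_per_m = a_kyr_per_m, b_kyr = b_kyr,
                 age_sigma_kyr = age_sigma_kyr, pools = pools,
                 loading_sdlog = loading_sdlog,
                 fraction_fun = fraction_fun, endmembers = endmembers,
                 d13c_sigma = d13c_sigma, d14c_sigma = d14c_sigma,
                 sampling_year = sampling_year,
                 csra_missing = as.integer(csra_missing), seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic shelf transect with known truth
#'
#' Draws one realization of the generative model in [synthetic_config()]
#' and returns both the station table (in the on-disk schema of
#' [read_stations()]) and a truth record sufficient for parameter-recovery
#' tests. Regenerating with the same config and seed is bit-identical.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `stations` (tibble) and `truth` (list holding the
#'   config, per-station true ages, transport times, noiseless loadings
#'   and source fractions).
#' @export
generate_transect <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_stations
  depth <- seq(cfg$depth_range[1], cfg$depth_range[2], length.out = n)
  tau_true <- cfg$a_kyr_per_m * depth
  age_true <- cfg$b_kyr + tau_true
  age_obs <- age_true + stats::rnorm(n, 0, cfg$age_sigma_kyr)

  fr <- t(vapply(depth, cfg$fraction_fun, numeric(3)))
  if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-9)) {
    stop("fraction trajectory leaves the simplex", call. = FALSE)
  }
  colnames(fr) <- cfg$endmembers$name

  # mixture means with the AL endmember decayed by each station's true tau
  d13_true <- numeric(n); d14_true <- numeric(n)
  for (i in seq_len(n)) {
    ems <- build_endmembers(cfg$endmembers, tau_kyr = tau_true[i],
                            sampling_year = cfg$sampling_year)
    d13_true[i] <- sum(fr[i, ] * ems$d13c)
    d14_true[i] <- sum(fr[i, ] * ems$d14c)
  }
  d13_obs <- d13_true + stats::rnorm(n, 0, cfg$d13c_sigma)
  d14_obs <- d14_true + stats::rnorm(n, 0, cfg$d14c_sigma)

  stations <- tibble::tibble(
    station_id = sprintf("SYN-%02d", seq_len(n)),
    depth_m = depth,
    sampling_year = cfg$sampling_year,
    d13c_toc = d13_obs, d13c_toc_sd = cfg$d13c_sigma,
    d14c_toc = d14_obs, d14c_toc_sd = cfg$d14c_sigma,
    csra_cal_age_kyr = age_obs,
    csra_cal_age_sd_kyr = cfg$age_sigma_kyr
  )
  miss <- cfg$csra_missing[cfg$csra_missing <= n]
  stations$csra_cal_age_kyr[miss] <- NA_real_
  stations$csra_cal_age_sd_kyr[miss] <- NA_real_

  loadings_true <- list()
  for (pn in names(cfg$pools)) {
    p <- cfg$pools[[pn]]
    mean_load <- p$c0 * (p$f_r + (1 - p$f_r) * exp(-p$k * tau_true))
    noise <- if (cfg$loading_sdlog > 0) {
      exp(stats::rnorm(n, 0, cfg$loading_sdlog))
    } else rep(1, n)
    stations[[paste0("loading_", pn)]] <- mean_load * noise
    stations[[paste0("loading_", pn, "_sd")]] <-
      mean_load * cfg$loading_sdlog
    loadings_true[[pn]] <- mean_load
  }

  list(stations = stations,
       truth = list(config = cfg, depth_m = depth, tau_kyr = tau_true,
                    age_true_kyr = age_true, age_obs_kyr = age_obs,
                    loadings_true = loadings_true, fractions = fr,
                    d13c_true = d13_true, d14c_true = d14_true,
                    seed = cfg$seed))
}

#' The bundled Laptev Sea transect station table
#'
#' The 11-station radiocarbon dataset for the Lena River to shelf-edge
#' transect (10 transect stations plus the river-mouth reference station
#' N-8 from an earlier study): water depth, bulk-OC Delta-14C, the
#' conventional bulk age, the calibrated compound-specific (long-chain
#' fatty acid) age where measured, and the derived net transport time.
#' Sampling years follow the two expeditions (2008 and 2014). Missing
#' values mark quantities not measured for that station.
#'
#' @return A tibble of 11 station records in the [read_stations()] schema
#'   plus the published conventional-age and transport-time columns
#'   (`c14_age_toc_kyr`, `transport_time_kyr`, and their sigmas) used for
#'   cross-checks.
#' @export
laptev_stations <- function() {
  path <- system.file("extdata", "laptev_stations.csv",
                      package = "shelfcarbon", mustWork = TRUE)
  read_stations(path)
}
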