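#' Default endmember priors for the three bulk-OC sources
#'
#' Literature dual-isotope signatures of the three sources that mix into
#' bulk sedimentary organic carbon on the East Siberian Arctic shelf:
#' active-layer permafrost (AL, fluvially delivered, seasonally thawed
#' topsoil), Ice Complex Deposit permafrost (ICD, late-Pleistocene
#' ice-rich deposits released by coastal erosion) and marine production.
#' Delta-14C values are the no-transport (near-shore) signatures; only the
#' AL endmember is decayed with transport time (see [build_endmembers()]):
#' the marine source is near-present and ICD carbon is so old that its
#' ageing is insensitive to where it happened.
#'
#' @return An `endmember_set` tibble with columns `name`, `d13c`,
#'   `d13c_sd`, `d14c`, `d14c_sd` (per mil), `time_dependent`.
#' @export
default_endmembers <- function() {
  structure(tibble::tibble(
    name = c("AL", "ICD", "marine"),
    d13c = c(-27.0, -26.3, -21.0),
    d13c_sd = c(1.2, 0.7, 2.5),
    d14c = c(-232, -940, -50),
    d14c_sd = c(147, 84, 12),
    time_dependent = c(TRUE, FALSE, FALSE)
  ), tau_kyr = 0, sampling_year = C14_REFERENCE_YEAR,
     class = c("endmember_set", "tbl_df", "tbl", "data.frame"))
}

#' Build the endmember set for a given transport time
#'
#' Ages the time-dependent (active-layer) endmember by the station's net
#' transport time: the Delta-14C mean and SD are converted to fraction
#' modern, both scaled by \eqn{e^{-\tau/8033}} (see [decay_signature()]),
#' and converted back — longer transport both depletes the endmember and
#' shrinks its variability. Time-independent endmembers pass through
#' unchanged.
#'
#' @param endmembers An `endmember_set` holding the no-transport priors;
#'   defaults to [default_endmembers()].
#' @param tau_kyr Net transport time in kyr (>= 0).
#' @param sampling_year Calendar year AD the sample was measured (the
#'   factor cancels in the decay round trip but is recorded for
#'   consistency checks against observations).
#' @return An `endmember_set` with the decayed Delta-14C columns and
#'   attributes `tau_kyr`, `sampling_year`.
#' @examples
#' build_endmembers(tau_kyr = 3.9)  # AL Delta-14C becomes ~ -527 ± 90
#' @export
build_endmembers <- function(endmembers = default_endmembers(), tau_kyr = 0,
                             sampling_year = 2010) {
  stopifnot(inherits(endmembers, "endmember_set"))
  if (tau_kyr < 0) stop("`tau_kyr` must be non-negative", call. = FALSE)
  if (length(unique(endmembers$name)) != 3L || nrow(endmembers) != 3L) {
    stop("an endmember set must hold exactly three distinct sources",
         call. = FALSE)
  }
  out <- endmembers
  tau_years <- tau_kyr * 1000
  for (i in which(out$time_dependent)) {
    fm0 <- delta14c_to_fm(qty(out$d14c[i], out$d14c_sd[i]), sampling_year)
    fmt <- decay_signature(fm0, tau_years)
    d <- fm_to_delta14c(fmt, sampling_year)
    out$d14c[i] <- d$value
    out$d14c_sd[i] <- d$sigma
  }
  attr(out, "tau_kyr") <- tau_kyr
  attr(out, "sampling_year") <- sampling_year
  out
}

#' A dual-isotope observation of bulk organic carbon
#'
#' @param d13c,d13c_sd Bulk delta-13C mean and 1-sigma (per mil).
#' @param d14c,d14c_sd Bulk Delta-14C mean and 1-sigma (per mil).
#' @param sampling_year Calendar year AD of sampling.
#' @return An `isotope_observation` list.
#' @export
isotope_observation <- function(d13c, d13c_sd, d14c, d14c_sd,
                                sampling_year = 2010) {
  if (d13c_sd <= 0 || d14c_sd <= 0) {
    stop("observation sigmas must be positive", call. = FALSE)
  }
  structure(list(d13c = qty(d13c, d13c_sd), d14c = qty(d14c, d14c_sd),
                 sampling_year = sampling_year),
            class = "isotope_observation")
}

#' Apportion one bulk-OC sample among three sources by MCMC
#'
#' Bayesian mixing model on the dual-carbon-isotope plane: the source
#' fractions \eqn{(f_{AL}, f_{ICD}, f_{marine})} live on the 2-simplex
#' with a flat prior; the six endmember isotope values are sampled
#' hierarchically with Normal priors at their stated means/SDs (so
#' endmember variability is marginalized, not fixed); each observed
#' tracer gets a Normal likelihood around the mixture mean
#' \eqn{\sum_i f_i EM_i} with the measurement SD. A random-walk
#' Metropolis chain proposes all parameters jointly; proposals leaving
#' the simplex are rejected, and the proposal scale is tuned to the
#' target acceptance during burn-in then frozen.
#'
#' @param obs An [isotope_observation()].
#' @param endmembers An `endmember_set`, typically from
#'   [build_endmembers()] at the station's transport time.
#' @param mcmc An [mcmc_config()] with a seed.
#' @return A `mixture_result`: `draws` (retained fraction draws, one
#'   column per source), `fractions` (summary tibble, mean ± SD),
#'   `f_terr` ([qty()], the AL + ICD sum per draw), `acceptance_rate`,
#'   `n_retained`, `seed`.
#' @export
apportion_sample <- function(obs, endmembers, mcmc = mcmc_config()) {
  stopifnot(inherits(obs, "isotope_observation"),
            inherits(endmembers, "endmember_set"))
  .require_seed(mcmc)
  yr_em <- attr(endmembers, "sampling_year")
  if (!is.null(yr_em) && !is.null(obs$sampling_year) &&
      yr_em != obs$sampling_year) {
    warning("observation and endmember set carry different sampling years",
            call. = FALSE)
  }
  em_mu <- c(endmembers$d13c, endmembers$d14c)
  em_sd <- c(endmembers$d13c_sd, endmembers$d14c_sd)
  if (any(em_sd <= 0)) stop("endmember sigmas must be positive", call. = FALSE)

  # start the chain at the mode of the endmember-marginalized posterior on
  # a coarse simplex grid: near-pure samples have razor-thin posteriors at
  # a vertex that a center-started random walk cannot reach while its
  # proposal scale is being tuned
  g0 <- grid_posterior_fractions(obs, endmembers, resolution = 0.02)
  mode <- which.max(g0$prob)
  f1_init <- g0[[1]][mode]
  f2_init <- g0[[2]][mode]

  set.seed(mcmc$seed)
  out <- mcmc_mixing_cpp(obs$d13c$value, obs$d13c$sigma,
                         obs$d14c$value, obs$d14c$sigma,
                         em_mu, em_sd,
                         mcmc$n_iterations, mcmc$burn_in, mcmc$thinning,
                         mcmc$target_acceptance, f1_init, f2_init)
  acc <- out$acceptance_rate
  if (!is.finite(acc) || acc < 0.1 || acc > 0.5) {
    stop(sprintf(paste0("apportionment sampler is untuned: realized ",
                        "acceptance %.3f outside [0.1, 0.5]"), acc),
         call. = FALSE)
  }
  draws <- out$draws
  colnames(draws) <- paste0("f_", endmembers$name)
  terr <- rowSums(draws[, endmembers$name != "marine", drop = FALSE])
  structure(list(
    draws = draws,
    fractions = tibble::tibble(
      source = endmembers$name,
      mean = unname(colMeans(draws)),
      sd = unname(apply(draws, 2, stats::sd))),
    f_terr = qty(mean(terr), stats::sd(terr)),
    acceptance_rate = acc,
    n_retained = nrow(draws),
    seed = mcmc$seed
  ), class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  cat("Dual-isotope source apportionment (", x$n_retained,
      " retained draws, acceptance ", sprintf("%.2f", x$acceptance_rate),
      ", seed ", x$seed, ")\n", sep = "")
  for (i in seq_len(nrow(x$fractions))) {
    cat(sprintf("  %-8s %.3f ± %.3f\n", x$fractions$source[i],
                x$fractions$mean[i], x$fractions$sd[i]))
  }
  cat("  f_terr  ", format(x$f_terr), "\n")
  invisible(x)
}

#' Terrestrial fraction of a mixture result
#'
#' The per-draw sum of the two permafrost fractions,
#' \eqn{f_{terr} = f_{AL} + f_{ICD} = 1 - f_{marine}}, summarized as
#' mean ± SD.
#'
#' @param mix A `mixture_result`.
#' @return A dimensionless [qty()].
#' @export
fraction_terroc <- function(mix) {
  stopifnot(inherits(mix, "mixture_result"))
  mix$f_terr
}

#' Repeatability check for the apportionment sampler
#'
#' Reruns the same apportionment with distinct seeds and reports the
#' relative standard deviation of the posterior-mean terrestrial
#' fraction across runs; the chain is considered converged when the RSD
#' is below 1%.
#'
#' @param obs An [isotope_observation()].
#' @param endmembers An `endmember_set`.
#' @param mcmc An [mcmc_config()]; run r uses `seed + r - 1`.
#' @param n_runs Number of repeats (>= 2, default 10).
#' @return A list: `rsd_percent`, `pass` (RSD < 1), `f_terr_means`,
#'   `seeds`.
#' @export
convergence_check <- function(obs, endmembers, mcmc = mcmc_config(),
                              n_runs = 10) {
  stopifnot(n_runs >= 2)
  .require_seed(mcmc)
  seeds <- mcmc$seed + seq_len(n_runs) - 1L
  means <- vapply(seeds, function(s) {
    m <- mcmc
    m$seed <- s
    apportion_sample(obs, endmembers, m)$f_terr$value
  }, numeric(1))
  rsd <- stats::sd(means) / mean(means) * 100
  list(rsd_percent = rsd, pass = rsd < 1, f_terr_means = means,
       seeds = seeds)
}

#' Exact grid posterior of the source fractions
#'
#' Independent cross-check for the MCMC sampler: with Normal endmember
#' priors the endmember values integrate out analytically, leaving each
#' observed tracer Normal around \eqn{\sum_i f_i \mu_i} with variance
#' \eqn{\sigma_{obs}^2 + \sum_i f_i^2 \sigma_{EM,i}^2}. This marginal
#' posterior is evaluated on a regular simplex grid and normalized.
#'
#' @param obs An [isotope_observation()].
#' @param endmembers An `endmember_set`.
#' @param resolution Grid step on the simplex (default 0.01).
#' @return A tibble of grid points (`f_<name>` columns) with
#'   probability masses `prob`; marginal posterior means are in the
#'   `means` attribute.
#' @export
grid_posterior_fractions <- function(obs, endmembers, resolution = 0.01) {
  stopifnot(inherits(obs, "isotope_observation"),
            inherits(endmembers, "endmember_set"))
  f1 <- seq(0, 1, by = resolution)
  g <- expand.grid(f1 = f1, f2 = f1)
  g <- g[g$f1 + g$f2 <= 1 + 1e-12, ]
  f3 <- pmax(0, 1 - g$f1 - g$f2)
  mix13 <- g$f1 * endmembers$d13c[1] + g$f2 * endmembers$d13c[2] +
    f3 * endmembers$d13c[3]
  mix14 <- g$f1 * endmembers$d14c[1] + g$f2 * endmembers$d14c[2] +
    f3 * endmembers$d14c[3]
  v13 <- obs$d13c$sigma^2 + g$f1^2 * endmembers$d13c_sd[1]^2 +
    g$f2^2 * endmembers$d13c_sd[2]^2 + f3^2 * endmembers$d13c_sd[3]^2
  v14 <- obs$d14c$sigma^2 + g$f1^2 * endmembers$d14c_sd[1]^2 +
    g$f2^2 * endmembers$d14c_sd[2]^2 + f3^2 * endmembers$d14c_sd[3]^2
  ll <- stats::dnorm(obs$d13c$value, mix13, sqrt(v13), log = TRUE) +
    stats::dnorm(obs$d14c$value, mix14, sqrt(v14), log = TRUE)
  p <- exp(ll - max(ll))
  p <- p / sum(p)
  out <- tibble::tibble(g$f1, g$f2, f3, p)
  names(out) <- c(paste0("f_", endmembers$name), "prob")
  attr(out, "means") <- stats::setNames(
    c(sum(p * g$f1), sum(p * g$f2), sum(p * f3)),
    paste0("f_", endmembers$name))
  out
}
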