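#' MCMC protocol settings
#'
#' One protocol is shared by the decay-kinetics fit and the
#' source-apportionment sampler: a long Metropolis chain with an initial
#' burn-in (discarded search phase, during which proposal scales are
#' adapted toward the target acceptance rate and then frozen), and
#' thinning to suppress autocorrelation between retained draws. The
#' defaults are the protocol used for all fits in the package: 10^6
#' iterations, 10^4 burn-in, thinning 10, acceptance tuned to ~0.23 (the
#' classic random-walk Metropolis optimum).
#'
#' @param n_iterations Total chain length (default 1e6).
#' @param burn_in Discarded initial iterations (default 1e4); must be
#'   shorter than the chain.
#' @param thinning Keep every `thinning`-th post-burn-in draw (default 10).
#' @param target_acceptance Proposal-scale tuning target in (0, 1),
#'   default 0.23.
#' @param seed Integer seed; mandatory for every stochastic fit.
#' @return An `mcmc_config` list. The retained-draw count is always
#'   `(n_iterations - burn_in) / thinning`.
#' @export
mcmc_config <- function(n_iterations = 1e6, burn_in = 1e4, thinning = 10,
                        target_acceptance = 0.23, seed = NULL) {
  stopifnot(n_iterations >= 1, burn_in >= 0, thinning >= 1)
  if (burn_in >= n_iterations) {
    stop("`burn_in` must be smaller than `n_iterations`", call. = FALSE)
  }
  if (target_acceptance <= 0 || target_acceptance >= 1) {
    stop("`target_acceptance` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 target_acceptance = target_acceptance,
                 seed = seed),
            class = "mcmc_config")
}

.require_seed <- function(mcmc) {
  if (is.null(mcmc$seed)) {
    stop("an integer `seed` must be set in the MCMC config", call. = FALSE)
  }
  invisible(mcmc)
}
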