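#' Diagnostic plot: age-depth scatter with the fitted line and band
#'
#' @param model A `transport_model`.
#' @param depth_m,age_kyr,age_sigma_kyr The fitted data.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_age_depth <- function(model, depth_m, age_kyr, age_sigma_kyr) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  grid <- seq(0, max(depth_m) * 1.05, length.out = 100)
  pred <- outer(model$b_draws, rep(1, length(grid))) +
    outer(model$a_draws, grid)
  band <- tibble::tibble(
    depth_m = grid,
    fit = colMeans(pred),
    lo = colMeans(pred) - 2 * apply(pred, 2, stats::sd),
    hi = colMeans(pred) + 2 * apply(pred, 2, stats::sd))
  pts <- tibble::tibble(depth_m = depth_m, age_kyr = age_kyr,
                        sd = age_sigma_kyr)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$depth_m)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "orange", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "orange") +
    ggplot2::geom_pointrange(
      data = pts,
      ggplot2::aes(y = .data$age_kyr, ymin = .data$age_kyr - .data$sd,
                   ymax = .data$age_kyr + .data$sd)) +
    ggplot2::labs(x = "Water depth (m)", y = "Calibrated age (kyr)")
}

#' Diagnostic plot: loading decay curve with the fit band
#'
#' @param fit A `decay_fit`.
#' @param series The fitted [pool_series()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_decay_fit <- function(fit, series) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  grid <- seq(0, max(series$tau_kyr) * 1.05, length.out = 100)
  idx <- seq(1, nrow(fit$draws),
             length.out = min(500, nrow(fit$draws)))
  curves <- vapply(grid, function(t) {
    v <- fit$draws[idx, "c_deg"] * exp(-fit$draws[idx, "k"] * t) +
      fit$draws[idx, "r_offset"]
    c(mean(v), stats::sd(v))
  }, numeric(2))
  band <- tibble::tibble(tau_kyr = grid, fit = curves[1, ],
                         lo = curves[1, ] - 2 * curves[2, ],
                         hi = curves[1, ] + 2 * curves[2, ])
  ggplot2::ggplot(band, ggplot2::aes(x = .data$tau_kyr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_pointrange(
      data = series,
      ggplot2::aes(y = .data$loading,
                   ymin = .data$loading - .data$loading_sigma,
                   ymax = .data$loading + .data$loading_sigma)) +
    ggplot2::labs(x = "Transport time (kyr)",
                  y = paste0("Loading (", fit$units, ")"),
                  title = fit$pool_name)
}
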