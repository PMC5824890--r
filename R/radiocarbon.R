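#' @title Radiocarbon algebra
#' @description Conversions between the Delta-14C scale, fraction modern and
#'   conventional radiocarbon age, decay of isotope signatures over a
#'   transport time, the dead-carbon methylation correction for fatty-acid
#'   methyl esters, and calendar calibration against a user-supplied curve.
#'
#'   All decay arithmetic is done in years internally; ages cross the
#'   interface in kyr. The single radiocarbon constant used throughout is
#'   the 8033-year mean life.
#' @name radiocarbon
NULL

#' Mean life of radiocarbon in years
#'
#' The e-folding decay time used in every conversion (conventional-age
#' definition, signature decay, Delta-14C reference-year factor).
#' @export
C14_MEAN_LIFE_YR <- 8033

#' Radiocarbon reference year (AD)
#' @rdname C14_MEAN_LIFE_YR
#' @export
C14_REFERENCE_YEAR <- 1950

#' Convert a Delta-14C measurement to fraction modern
#'
#' Inverts the definition
#' \deqn{\Delta^{14}C = (f_m e^{(1950-yr)/8033} - 1) \times 1000}
#' so that \eqn{f_m = (1 + \Delta/1000) e^{(yr-1950)/8033}}, where `yr` is
#' the year the sample was measured (the sample keeps decaying between 1950
#' and the measurement). Uncertainty is propagated to first order:
#' \eqn{\sigma_{fm} = \sigma_\Delta/1000 \cdot e^{(yr-1950)/8033}}.
#'
#' @param delta14c Per-mil Delta-14C as a [qty()] (or numeric, coerced).
#'   Must be \eqn{\ge -1000}.
#' @param sampling_year Calendar year AD of sampling; must be
#'   \eqn{\ge 1950}.
#' @return Fraction modern as a `qty` (dimensionless, \eqn{\ge 0}).
#' @examples
#' delta14c_to_fm(qty(-364, 2), 2014)  # ~0.641
#' @seealso [fm_to_delta14c()], [conventional_age()]
#' @export
delta14c_to_fm <- function(delta14c, sampling_year = C14_REFERENCE_YEAR) {
  d <- as_qty(delta14c)
  if (d$value < -1000) {
    stop("Delta-14C below -1000 per mil is not a physical isotope value",
         call. = FALSE)
  }
  if (sampling_year < C14_REFERENCE_YEAR) {
    stop("`sampling_year` must not precede the 1950 reference year",
         call. = FALSE)
  }
  g <- exp((sampling_year - C14_REFERENCE_YEAR) / C14_MEAN_LIFE_YR)
  qty((1 + d$value / 1000) * g, d$sigma / 1000 * g)
}

#' Convert fraction modern to Delta-14C
#'
#' Exact inverse of [delta14c_to_fm()]; the round trip is an identity to
#' machine precision.
#'
#' @param fm Fraction modern as a [qty()] (or numeric); must be
#'   \eqn{\ge 0}.
#' @inheritParams delta14c_to_fm
#' @return Per-mil Delta-14C as a `qty`.
#' @export
fm_to_delta14c <- function(fm, sampling_year = C14_REFERENCE_YEAR) {
  f <- as_qty(fm)
  if (f$value < 0) stop("fraction modern must be non-negative", call. = FALSE)
  g <- exp((C14_REFERENCE_YEAR - sampling_year) / C14_MEAN_LIFE_YR)
  qty((f$value * g - 1) * 1000, f$sigma * g * 1000)
}

#' Conventional radiocarbon age from fraction modern
#'
#' \eqn{age = -8.033\,\mathrm{kyr} \times \ln f_m}, with the first-order
#' uncertainty \eqn{\sigma_{age} = 8.033\,\sigma_{fm}/f_m}.
#'
#' @param fm Fraction modern as a [qty()] (or numeric); must be > 0.
#' @return Conventional age in kyr as a `qty`.
#' @examples
#' fm <- delta14c_to_fm(qty(-364, 2), 2014)
#' conventional_age(fm)  # ~3.57 kyr
#' @export
conventional_age <- function(fm) {
  f <- as_qty(fm)
  if (f$value <= 0) {
    stop("fraction modern must be positive (dead carbon has infinite age)",
         call. = FALSE)
  }
  ml_kyr <- C14_MEAN_LIFE_YR / 1000
  qty(-ml_kyr * log(f$value), ml_kyr * f$sigma / f$value)
}

#' Decay a fraction-modern signature over a transport time
#'
#' Both the mean and the standard deviation of a fraction-modern
#' distribution scale by \eqn{e^{-\tau/8033}} after `tau` years of decay:
#' \eqn{\mu_\tau = \mu_0 e^{-\tau/8033}}, \eqn{\sigma_\tau = \sigma_0
#' e^{-\tau/8033}}. Used to age the active-layer endmember by a station's
#' transport time before mixing.
#'
#' @param fm Fraction modern as a [qty()] (mean and 1-sigma).
#' @param tau_years Elapsed time in years, \eqn{\ge 0}.
#' @return The decayed fraction modern as a `qty`.
#' @export
decay_signature <- function(fm, tau_years) {
  f <- as_qty(fm)
  stopifnot(is.numeric(tau_years), length(tau_years) == 1L)
  if (tau_years < 0) stop("`tau_years` must be non-negative", call. = FALSE)
  g <- exp(-tau_years / C14_MEAN_LIFE_YR)
  qty(f$value * g, f$sigma * g)
}

#' Correct a FAME fraction modern for the methylation-added carbon
#'
#' Fatty acids are measured as methyl esters (FAMEs); the derivatization
#' adds one methyl carbon per molecule, radiocarbon-dead when the methanol
#' is petrochemical. Isotope mass balance over the n + 1 FAME carbons gives
#' the underlying fatty-acid signature:
#' \deqn{f_{fa} = \frac{f_{FAME} (n + 1) - f_{added}}{n}}
#' where `n` is the (abundance-weighted mean) fatty-acid carbon number of
#' the pooled homologs.
#'
#' @param fm_fame Measured FAME fraction modern as a [qty()].
#' @param mean_fa_carbons Mean fatty-acid chain length n (\eqn{\ge 1});
#'   for pooled C24-C30 homologs use the abundance-weighted mean.
#' @param fm_added Fraction modern of the methylation carbon; defaults to
#'   `qty(0, 0)` (radiocarbon-dead methanol).
#' @return Fraction modern of the fatty acid as a `qty`; errors if the
#'   mass balance yields a negative value.
#' @examples
#' methylation_correct(qty(0.48, 0.01), 24)  # 0.50
#' @export
methylation_correct <- function(fm_fame, mean_fa_carbons,
                                fm_added = qty(0, 0)) {
  f <- as_qty(fm_fame); a <- as_qty(fm_added)
  stopifnot(is.numeric(mean_fa_carbons), length(mean_fa_carbons) == 1L)
  if (mean_fa_carbons < 1) {
    stop("`mean_fa_carbons` must be at least 1", call. = FALSE)
  }
  n <- mean_fa_carbons
  v <- (f$value * (n + 1) - a$value) / n
  if (v < 0) {
    stop("methylation correction yields a negative fraction modern; ",
         "inputs are inconsistent", call. = FALSE)
  }
  qty(v, sqrt((f$sigma * (n + 1) / n)^2 + (a$sigma / n)^2))
}

#' Read a calibration curve from a plain-text file
#'
#' Expects the dialect of published calibration-curve distributions: lines
#' starting with `#` are comments; data rows are comma- or
#' whitespace-separated with three columns — calendar age BP, conventional
#' 14C age BP, and the curve's 1-sigma (all in years).
#'
#' @param path Path to the curve file.
#' @return A `cal_curve`: a tibble with columns `cal_bp`, `c14_bp`,
#'   `sigma`, sorted by increasing `cal_bp`.
#' @export
read_calibration_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("calibration curve file is empty", call. = FALSE)
  fields <- strsplit(lines, "[,[:space:]]+")
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0) {
    stop("malformed calibration-curve row (need 3 columns) at data line ",
         bad[1], call. = FALSE)
  }
  m <- vapply(fields, function(f) as.numeric(f[1:3]), numeric(3))
  calibration_curve(m[1, ], m[2, ], m[3, ])
}

#' Construct a calibration curve from vectors
#'
#' @param cal_bp Calendar ages BP (strictly monotone).
#' @param c14_bp Conventional 14C ages BP at those calendar ages.
#' @param sigma Curve 1-sigma in years (non-negative).
#' @return A `cal_curve` tibble.
#' @export
calibration_curve <- function(cal_bp, c14_bp, sigma) {
  stopifnot(length(cal_bp) == length(c14_bp),
            length(cal_bp) == length(sigma), length(cal_bp) >= 2)
  if (anyNA(cal_bp) || anyNA(c14_bp) || anyNA(sigma)) {
    stop("calibration curve contains missing values", call. = FALSE)
  }
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]; c14_bp <- c14_bp[o]; sigma <- sigma[o]
  if (any(diff(cal_bp) <= 0)) {
    stop("calendar ages must be strictly monotone", call. = FALSE)
  }
  if (any(sigma < 0)) stop("curve sigma must be non-negative", call. = FALSE)
  structure(tibble::tibble(cal_bp = cal_bp, c14_bp = c14_bp, sigma = sigma),
            class = c("cal_curve", "tbl_df", "tbl", "data.frame"))
}

#' Calibrate a conventional radiocarbon age
#'
#' Computes the posterior density over calendar age on a grid spanning the
#' curve: at calendar age \eqn{\theta}, the density is proportional to a
#' normal likelihood of the (reservoir-corrected) conventional age at the
#' curve's 14C age \eqn{\mu(\theta)} with variance
#' \eqn{\sigma_{age}^2 + \sigma_{curve}(\theta)^2 + \sigma_{\Delta R}^2}.
#' The curve and its sigma are interpolated linearly between knots. The
#' point estimate is the probability-weighted mean and SD; a 95%
#' highest-density interval is also returned.
#'
#' @param conv_age Conventional age in kyr as a [qty()].
#' @param curve A `cal_curve` from [read_calibration_curve()] or
#'   [calibration_curve()].
#' @param delta_r Marine reservoir offset in years as a [qty()]; default
#'   `qty(0, 0)`.
#' @param resolution Grid step in years for the posterior; defaults to the
#'   smaller of 1 year and the curve's knot spacing.
#' @return A `cal_age`: list with `point` (kyr `qty`), `pdf` (tibble of
#'   `cal_bp` and probability mass `prob` summing to 1), and `hdi95`
#'   (years BP).
#' @export
calibrate <- function(conv_age, curve, delta_r = qty(0, 0),
                      resolution = NULL) {
  a <- as_qty(conv_age); dr <- as_qty(delta_r)
  stopifnot(inherits(curve, "cal_curve"))
  age_yr <- a$value * 1000 - dr$value
  sig_yr <- sqrt((a$sigma * 1000)^2 + dr$sigma^2)
  # coverage: the curve's 14C ages must bracket the measurement +/- 4 sigma
  if (age_yr - 4 * sig_yr < min(curve$c14_bp) ||
      age_yr + 4 * sig_yr > max(curve$c14_bp)) {
    stop("conventional age (± 4 sigma) lies outside the calibration ",
         "curve's 14C-age coverage", call. = FALSE)
  }
  if (is.null(resolution)) {
    resolution <- max(min(1, min(diff(curve$cal_bp))),
                      diff(range(curve$cal_bp)) / 1e5)
  }
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = resolution)
  mu <- stats::approx(curve$cal_bp, curve$c14_bp, xout = grid)$y
  sc <- stats::approx(curve$cal_bp, curve$sigma, xout = grid)$y
  w <- stats::dnorm(age_yr, mean = mu, sd = sqrt(sig_yr^2 + sc^2))
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    stop("calibration produced a degenerate posterior", call. = FALSE)
  }
  p <- w / total
  mean_bp <- sum(p * grid)
  sd_bp <- sqrt(sum(p * (grid - mean_bp)^2))
  # 95% highest-density set on the grid
  o <- order(p, decreasing = TRUE)
  keep <- o[seq_len(which(cumsum(p[o]) >= 0.95)[1])]
  structure(list(
    point = qty(mean_bp / 1000, sd_bp / 1000),
    pdf = tibble::tibble(cal_bp = grid, prob = p),
    hdi95 = range(grid[keep])
  ), class = "cal_age")
}

#' @export
print.cal_age <- function(x, ...) {
  cat("Calibrated age:", format(x$point), "kyr BP",
      sprintf("[95%% HDI %.0f-%.0f yr BP]\n", x$hdi95[1], x$hdi95[2]))
  invisible(x)
}
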