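#' Normalize a concentration to mineral specific surface area
#'
#' Loadings are expressed per m2 of mineral surface rather than per gram
#' of sediment, because surface area is conservative during transport
#' while grain-size composition is not. Uncertainties combine in
#' quadrature of the relative errors.
#'
#' @param concentration Mass per gram dry sediment as a [qty()].
#' @param surface_area m2 per gram as a [qty()]; must be positive.
#' @return Loading per m2 as a `qty`.
#' @examples
#' normalize_to_sa(qty(1000, 100), qty(20, 1))  # 50 ± 5.6
#' @export
normalize_to_sa <- function(concentration, surface_area) {
  sa <- as_qty(surface_area)
  if (sa$value <= 0) {
    stop("mineral surface area must be positive", call. = FALSE)
  }
  qty_divide(as_qty(concentration), sa)
}

#' Depth-dependent fine-fraction model
#'
#' Describes which share of a pool resides in the transport-prone fine
#' (<63 um) sediment fraction as a function of water depth, used to
#' correct whole-sediment loadings for hydrodynamic sorting. The
#' coefficients come from an external fine-fraction dataset and are
#' supplied through the run configuration; the `passthrough` form (the
#' default throughout the package) applies no correction.
#'
#' @param form `"passthrough"`, `"linear"` (fraction =
#'   `coefficients[1] + coefficients[2] * depth`) or `"logistic"`
#'   (fraction = `1 / (1 + exp(-(coefficients[1] + coefficients[2] *
#'   depth)))`).
#' @param coefficients Numeric coefficients of the chosen form.
#' @param depth_range Valid depth range in meters; predictions outside it
#'   raise an extrapolation warning.
#' @return A `fine_fraction_model`.
#' @export
fine_fraction_model <- function(form = c("passthrough", "linear", "logistic"),
                                coefficients = numeric(),
                                depth_range = c(0, Inf)) {
  form <- match.arg(form)
  if (form != "passthrough" && length(coefficients) < 2) {
    stop("`coefficients` must supply an intercept and a depth slope",
         call. = FALSE)
  }
  structure(list(form = form, coefficients = coefficients,
                 depth_range = depth_range),
            class = "fine_fraction_model")
}

#' Predict the fine-fraction share at a depth
#' @param model A [fine_fraction_model()].
#' @param depth_m Water depth in meters.
#' @return The modeled fraction in (0, 1].
#' @export
predict_fine_fraction <- function(model, depth_m) {
  stopifnot(inherits(model, "fine_fraction_model"))
  extrapolating <- depth_m < model$depth_range[1] ||
    depth_m > model$depth_range[2]
  if (extrapolating) {
    warning("depth ", depth_m, " m is outside the fine-fraction model's ",
            "valid range; extrapolating (share clamped to (0, 1])",
            call. = FALSE)
  }
  f <- switch(model$form,
    passthrough = 1,
    linear = model$coefficients[1] + model$coefficients[2] * depth_m,
    logistic = 1 / (1 + exp(-(model$coefficients[1] +
                                model$coefficients[2] * depth_m)))
  )
  if (extrapolating) return(min(max(f, 1e-6), 1))
  if (f <= 0 || f > 1) {
    stop("fine-fraction model predicts a share outside (0, 1] at ",
         depth_m, " m", call. = FALSE)
  }
  f
}

#' Correct a loading for hydrodynamic sorting
#'
#' Multiplies a whole-sediment loading by the modeled share residing in
#' the fine fraction at the station's depth. With the default
#' passthrough model this is the identity.
#'
#' @param loading A [qty()] loading (typically surface-area normalized
#'   first; normalization precedes this correction).
#' @param depth_m Water depth in meters.
#' @param model A [fine_fraction_model()].
#' @return The corrected loading as a `qty`.
#' @export
apply_fine_fraction <- function(loading, depth_m,
                                model = fine_fraction_model()) {
  f <- predict_fine_fraction(model, depth_m)
  qty_scale(as_qty(loading), f)
}

#' Chain-length ratio diagnostics for n-fatty acids
#'
#' The short-chain (C16-C18, partly marine) to long-chain (C24-C30,
#' terrestrial plant-wax) fatty-acid ratio tracks the growing marine
#' share of organic matter offshore; an increase with depth is the
#' expected marine-dilution signal. Uncertainties propagate in
#' quadrature (sums of homolog sigmas, then the ratio).
#'
#' @param fa_concentrations Named list/vector of per-homolog
#'   concentrations; names are chain lengths (`"16"`, `"C16"`, ...),
#'   values [qty()]s or numerics. At least one short (16-18) and one long
#'   (24-30) homolog are required.
#' @return A list: `short_long_ratio` and `lmw_hmw_ratio` ([qty()]s;
#'   identical partitions here, both reported for convention), `short_sum`,
#'   `long_sum`.
#' @export
chain_length_ratios <- function(fa_concentrations) {
  lens <- as.integer(gsub("[^0-9]", "", names(fa_concentrations)))
  if (anyNA(lens)) {
    stop("homolog names must encode the chain length (e.g. \"C24\")",
         call. = FALSE)
  }
  qs <- lapply(fa_concentrations, as_qty)
  sum_q <- function(idx) {
    if (!any(idx)) return(NULL)
    qty(sum(vapply(qs[idx], function(q) q$value, 1)),
        sqrt(sum(vapply(qs[idx], function(q) q$sigma^2, 1))))
  }
  short <- sum_q(lens >= 16 & lens <= 18)
  long <- sum_q(lens >= 24 & lens <= 30)
  if (is.null(short) || is.null(long)) {
    stop("need at least one short (C16-C18) and one long (C24-C30) homolog",
         call. = FALSE)
  }
  if (long$value == 0) {
    stop("long-chain sum is zero; ratio undefined", call. = FALSE)
  }
  ratio <- qty_divide(short, long)
  list(short_long_ratio = ratio, lmw_hmw_ratio = ratio,
       short_sum = short, long_sum = long)
}
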