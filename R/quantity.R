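#' Value with 1-sigma uncertainty
#'
#' The universal currency of the package: every measured or derived scalar
#' (an isotope value, an age, a loading, a rate constant) travels as a value
#' plus a one-standard-deviation uncertainty. Units are carried by context
#' and documented at each interface.
#'
#' @param value Numeric scalar (finite).
#' @param sigma Non-negative numeric scalar, the 1-sigma uncertainty.
#'   Defaults to 0 (exactly known).
#' @return An object of class `qty`: a list with elements `value` and
#'   `sigma`.
#' @examples
#' qty(-364, 2)   # a Delta-14C measurement in per mil
#' qty(9.99, 0.34) # a calibrated age in kyr
#' @export
qty <- function(value, sigma = 0) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            is.numeric(sigma), length(sigma) == 1L)
  if (!is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be a finite non-negative number", call. = FALSE)
  }
  structure(list(value = as.numeric(value), sigma = as.numeric(sigma)),
            class = "qty")
}

#' @export
print.qty <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.qty <- function(x, digits = 4, ...) {
  paste0(signif(x$value, digits), " ± ", signif(x$sigma, digits))
}

#' @rdname qty
#' @param x Object to test or coerce.
#' @export
is_qty <- function(x) inherits(x, "qty")

#' @rdname qty
#' @details `as_qty()` accepts an existing `qty`, a length-1 numeric
#'   (sigma 0), or a length-2 numeric `c(value, sigma)`.
#' @export
as_qty <- function(x) {
  if (is_qty(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(qty(x, 0))
  if (is.numeric(x) && length(x) == 2L) return(qty(x[1], x[2]))
  stop("cannot interpret `x` as a value ± sigma pair", call. = FALSE)
}

# relative error helper used by quadrature propagation; 0/0 -> 0
.rel_err <- function(q) if (q$value == 0) 0 else q$sigma / abs(q$value)

#' Multiply or divide quantities with quadrature error propagation
#'
#' First-order (delta-method) propagation for products and ratios of
#' independent quantities: relative errors add in quadrature.
#'
#' @param a,b `qty` objects (or numerics coercible via [as_qty()]).
#' @return A `qty`.
#' @keywords internal
#' @export
qty_divide <- function(a, b) {
  a <- as_qty(a); b <- as_qty(b)
  if (b$value == 0) stop("division by a zero-valued quantity", call. = FALSE)
  v <- a$value / b$value
  qty(v, abs(v) * sqrt(.rel_err(a)^2 + .rel_err(b)^2))
}

#' @rdname qty_divide
#' @export
qty_multiply <- function(a, b) {
  a <- as_qty(a); b <- as_qty(b)
  v <- a$value * b$value
  qty(v, abs(v) * sqrt(.rel_err(a)^2 + .rel_err(b)^2))
}

#' @rdname qty_divide
#' @param k Numeric scalar.
#' @export
qty_scale <- function(a, k) {
  a <- as_qty(a)
  qty(a$value * k, a$sigma * abs(k))
}
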