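#' Specification of the transfer-function spline basis
#'
#' Every transfer function \eqn{h^{mk}} is a cubic spline spanned by
#' B-spline basis functions on a fixed grid of simple (unrepeated)
#' equidistant knots.  With \code{n_knots} simple knots and order 4 the
#' basis has \code{n_knots - 4} functions; the default 8 knots from -400
#' to 1000 bp give 4 basis functions, so each pairwise transfer function
#' carries 4 free coefficients.  The value of the largest knot caps the
#' range of detectable dependence (1000 bp downstream by default); the
#' negative-knot extension only exists so that \eqn{h(0)} need not vanish
#' — \eqn{h} is evaluated at nonnegative lags.
#'
#' @param first_knot,last_knot Range of the knot grid in bp.
#' @param n_knots Number of equidistant knots.
#' @param order Spline order (4 = cubic).
#' @return An object of class \code{SplineSpec} with elements
#'   \code{knots}, \code{order}, \code{d_beta} and \code{support}
#'   (\code{c(0, last_knot)}).
#' @export
spline_spec <- function(first_knot = -400, last_knot = 1000,
                        n_knots = 8, order = 4) {
  stopifnot(last_knot > first_knot, n_knots > order, order >= 1)
  knots <- seq(first_knot, last_knot, length.out = n_knots)
  structure(list(knots = knots, order = as.integer(order),
                 d_beta = as.integer(n_knots - order),
                 support = c(0, last_knot)),
            class = "SplineSpec")
}

#' Evaluate the B-spline basis at lags
#'
#' Returns the matrix of basis values \eqn{B_l(t)}, one row per lag and
#' one column per basis function.  All values are nonnegative; rows are
#' identically zero for lags at or beyond the last knot and below the
#' first knot (each basis function's support is half-open on the right).
#'
#' @param t Lag values in bp (vectorized; any finite values allowed).
#' @param spec A [spline_spec()].
#' @return Numeric matrix, \code{length(t)} by \code{spec$d_beta}.
#' @export
evaluate_basis <- function(t, spec = spline_spec()) {
  stopifnot(inherits(spec, "SplineSpec"), all(is.finite(t)))
  out <- matrix(0, length(t), spec$d_beta)
  inside <- t >= spec$knots[1L] & t < spec$knots[length(spec$knots)]
  if (any(inside)) {
    out[inside, ] <- splines::splineDesign(spec$knots, t[inside],
                                           ord = spec$order,
                                           outer.ok = TRUE)
  }
  out
}

#' Evaluate a transfer function h(t) = beta' B(t)
#'
#' @param t Lags in bp (vectorized).
#' @param beta Coefficient vector of length \code{spec$d_beta}.
#' @param spec A [spline_spec()].
#' @return Numeric vector of \eqn{h} values; zero outside the knot range.
#' @export
evaluate_h <- function(t, beta, spec = spline_spec()) {
  if (length(beta) != spec$d_beta) {
    stop("beta must have length ", spec$d_beta, ", got ", length(beta))
  }
  drop(evaluate_basis(t, spec) %*% beta)
}

#' @exportS3Method base::print
print.SplineSpec <- function(x, ...) {
  cat("SplineSpec: order", x$order, "B-spline basis,", x$d_beta,
      "function(s) on", length(x$knots), "simple knots in [",
      x$knots[1L], ",", x$knots[length(x$knots)], "] bp\n")
  invisible(x)
}
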