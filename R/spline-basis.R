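#' Specification of a natural cubic spline basis
#'
#' `df` counts basis columns excluding the intercept (the common reading of
#' "a natural cubic spline with seven degrees of freedom"). Interior knots
#' default to equally spaced quantiles of the data; boundary knots to the
#' data range. Natural boundary conditions make the fitted curve linear
#' beyond the boundary knots, which keeps extrapolated fitness curves
#' tame at extreme temperatures.
#'
#' @param df Degrees of freedom (basis columns), >= 3.
#' @param knots Optional interior knot positions (degC), strictly
#'   increasing.
#' @param boundary Optional `c(min, max)` boundary knots (degC).
#' @return A `spline_spec` list.
#' @export
spline_spec <- function(df = 7L, knots = NULL, boundary = NULL) {
  df <- as.integer(df)
  if (df < 3L) stop("spline df must be >= 3")
  if (!is.null(knots) && is.unsorted(knots, strictly = TRUE))
    stop("interior knots must be strictly increasing")
  if (!is.null(boundary)) {
    stopifnot(length(boundary) == 2L, boundary[1L] < boundary[2L])
    if (!is.null(knots) &&
        (min(knots) <= boundary[1L] || max(knots) >= boundary[2L]))
      stop("interior knots must lie strictly inside the boundary")
  }
  structure(list(df = df, knots = knots, boundary = boundary),
            class = "spline_spec")
}

#' Natural cubic spline basis matrix
#'
#' Evaluates the natural cubic spline basis of a [spline_spec] at `x`.
#' The returned matrix carries the realized knots as attributes so the
#' identical basis can be re-evaluated on a prediction grid or inside a
#' bootstrap refit.
#'
#' @param x Numeric vector (temperatures, degC).
#' @param spec A [spline_spec].
#' @return Matrix with `spec$df` columns and attributes `knots`,
#'   `Boundary.knots`.
#' @export
natural_cubic_spline_basis <- function(x, spec = spline_spec()) {
  stopifnot(inherits(spec, "spline_spec"))
  if (length(unique(x[is.finite(x)])) < spec$df + 1L)
    stop("need more than df distinct values to place the knots")
  if (is.null(spec$knots)) {
    b <- splines::ns(x, df = spec$df,
                     Boundary.knots = spec$boundary %||% range(x))
  } else {
    b <- splines::ns(x, knots = spec$knots,
                     Boundary.knots = spec$boundary %||% range(x))
  }
  out <- unclass(b)
  attributes(out) <- attributes(out)[c("dim", "dimnames", "knots",
                                       "Boundary.knots")]
  colnames(out) <- paste0("ns", seq_len(ncol(out)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Re-evaluate a basis (by its stored knots) at new x.
basis_eval <- function(x, basis) {
  out <- unclass(splines::ns(x, knots = attr(basis, "knots"),
                             Boundary.knots = attr(basis, "Boundary.knots")))
  colnames(out) <- paste0("ns", seq_len(ncol(out)))
  out
}
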