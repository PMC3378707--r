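#' B-spline specification for a mean trajectory
#'
#' Describes the fixed-effects basis used for the component mean curves: an
#' explicit intercept plus `df` B-spline basis functions of time with degree
#' `min(3, df)` (so flexibility beyond cubic is gained through knots, not
#' degree). Interior knots are placed at equally spaced quantiles of the
#' supplied times, which concentrates flexibility where measurement occasions
#' are dense — longitudinal trial schedules are typically front-loaded.
#' Boundary knots sit at the range of the supplied times; evaluation outside
#' the boundary is an error, not extrapolation.
#'
#' @param times Numeric vector of observation times the basis is anchored to.
#' @param df Integer 1--5, number of spline basis functions in addition to
#'   the intercept.
#' @param boundary Optional length-2 boundary override.
#' @return An object of class `"censmix_spline"`: list with `df`, `degree`,
#'   `knots`, `boundary`.
#' @examples
#' sp <- spline_spec(0:10, df = 4)
#' sp$degree   # 3
#' sp$knots    # one interior knot at the median
#' @export
spline_spec <- function(times, df, boundary = NULL) {
  df <- as.integer(df)
  if (df < 1L || df > 5L) stop("`df` must be between 1 and 5")
  if (!all(is.finite(times))) stop("`times` must be finite")
  if (is.null(boundary)) boundary <- range(times)
  if (boundary[1L] >= boundary[2L]) stop("degenerate time range")
  degree <- min(3L, df)
  n_iknots <- df - degree
  knots <- numeric(0)
  if (n_iknots > 0L) {
    probs <- seq(0, 1, length.out = n_iknots + 2L)[-c(1L, n_iknots + 2L)]
    knots <- as.numeric(stats::quantile(times, probs, names = FALSE))
  }
  structure(
    list(df = df, degree = degree, knots = knots,
         boundary = as.numeric(boundary)),
    class = "censmix_spline"
  )
}

#' Evaluate the design basis of a spline specification
#'
#' Returns the `n x (df + 1)` fixed-effects design matrix: a column of ones
#' followed by the `df` B-spline columns. The spline block omits the basis
#' function that would be collinear with the intercept.
#'
#' @param times Evaluation times; must lie inside the boundary knots (a
#'   relative tolerance of 1e-8 absorbs rounding).
#' @param spec A [spline_spec()] object.
#' @return Numeric matrix with `length(times)` rows and `spec$df + 1` columns.
#' @export
spline_basis <- function(times, spec) {
  stopifnot(inherits(spec, "censmix_spline"))
  b <- spec$boundary
  tol <- 1e-8 * max(1, abs(b[2L] - b[1L]))
  if (any(times < b[1L] - tol | times > b[2L] + tol)) {
    stop(
      "times outside the spline boundary [", b[1L], ", ", b[2L],
      "]; no extrapolation"
    )
  }
  times <- pmin(pmax(times, b[1L]), b[2L])
  B <- splines::bs(
    times, knots = spec$knots, degree = spec$degree,
    Boundary.knots = b, intercept = FALSE
  )
  X <- cbind(1, unname(B[, , drop = FALSE]))
  colnames(X) <- c("(Intercept)", paste0("bs", seq_len(spec$df)))
  X
}

#' Component mean curve at given times
#'
#' @param spec A [spline_spec()] object.
#' @param alpha Coefficient vector of length `spec$df + 1` (intercept first).
#' @param times Evaluation times within the spline boundary.
#' @return Numeric vector `spline_basis(times, spec) %*% alpha`.
#' @export
mean_curve <- function(spec, alpha, times) {
  if (length(alpha) != spec$df + 1L) {
    stop("`alpha` must have length df + 1 = ", spec$df + 1L)
  }
  drop(spline_basis(times, spec) %*% alpha)
}
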