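#' Cubic B-spline basis for the size-survival curve
#'
#' Builds the cubic B-spline basis used for the nonparametric effect of
#' body size on survival: interior knots at quantiles of the observed sizes
#' (by default the 10th, 30th, 50th, 70th and 90th percentiles), evaluated
#' either at the data or on a reference grid.  Columns are centered on
#' their grid means (a sum-to-zero constraint over the grid) so the curve
#' carries no intercept and the sex-specific survival intercepts stay
#' identifiable.
#'
#' @param x numeric vector of sizes (mm) at which to evaluate the basis.
#' @param knots_from sizes from which interior knots are taken (defaults to
#'   `x`); must contain more distinct values than the number of knots.
#' @param n_knots number of interior knots.
#' @param degree spline degree (3 = cubic).
#' @param boundary boundary knots; defaults to the range of `knots_from`
#'   padded by 5%.
#' @param center subtract column means (computed over `x`)?
#' @return basis matrix with attributes `knots`, `boundary` and (when
#'   centered) `center`.
#' @export
spline_basis <- function(x, knots_from = x, n_knots = 5, degree = 3,
                         boundary = NULL, center = TRUE) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be finite and positive")
  if (length(unique(knots_from)) <= n_knots)
    stop("fewer distinct size values than knots")
  probs <- seq(0.1, 0.9, length.out = n_knots)
  kn <- stats::quantile(knots_from, probs, names = FALSE)
  if (is.null(boundary)) {
    r <- range(knots_from)
    pad <- 0.05 * diff(r)
    boundary <- c(r[1] - pad, r[2] + pad)
  }
  B <- splines::bs(x, knots = kn, degree = degree, intercept = TRUE,
                   Boundary.knots = boundary)
  B <- matrix(as.numeric(B), nrow(B), ncol(B))
  ctr <- NULL
  if (center) {
    ctr <- colMeans(B)
    B <- sweep(B, 2, ctr)
  }
  attr(B, "knots") <- kn
  attr(B, "boundary") <- boundary
  attr(B, "center") <- ctr
  B
}
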