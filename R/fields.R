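# Shared raster numerics: every image, edge map, stop function and level-set
# function in this package is a plain numeric matrix ("scalar field") indexed
# [row, col].  World coordinates are zero-based with x = column index, y = row
# index and the origin at the top-left pixel centre, so pixel [r, c] sits at
# (x, y) = (c - 1, r - 1).

#' Validate a scalar field
#'
#' Checks that `f` is a finite numeric matrix with at least 3 rows and 3
#' columns (the finite-difference stencils need interior points).
#'
#' @param f A numeric matrix.
#' @param name Name used in error messages.
#' @return `f`, invisibly.
#' @export
check_field <- function(f, name = "field") {
  if (!is.matrix(f) || !is.numeric(f))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (nrow(f) < 3L || ncol(f) < 3L)
    stop(name, " must be at least 3 x 3", call. = FALSE)
  if (!all(is.finite(f)))
    stop(name, " contains non-finite values", call. = FALSE)
  invisible(f)
}

#' Pixel-centre coordinate grids
#'
#' @param shape Integer vector `c(height, width)`.
#' @return List with matrices `x` (column index minus one) and `y` (row index
#'   minus one), each of dimension `shape`.
#' @export
coord_grids <- function(shape) {
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  list(
    x = matrix(rep(seq_len(w) - 1, each = h), h, w),
    y = matrix(rep(seq_len(h) - 1, times = w), h, w)
  )
}

# Normalized 1-D Gaussian taps at integer offsets -r..r, r = ceiling(3*sigma)
# (at least 1).  Unit mass, so convolution preserves constants exactly.
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Symmetric (edge-repeating) reflection pad indices for length n, radius r.
reflect_pad_index <- function(n, r) {
  r <- min(r, n - 1L)
  c(seq(r, 1L), seq_len(n), seq(n, n - r + 1L))
}

#' Gaussian smoothing of a scalar field
#'
#' Separable convolution with a sampled, unit-mass Gaussian kernel, radius
#' `ceiling(3*sigma)`, using symmetric reflection at the borders.  Constants
#' are preserved exactly and the field mean is preserved for inputs supported
#' away from the borders.
#'
#' @param f Scalar field (numeric matrix).
#' @param sigma Kernel standard deviation in pixels; must be positive.
#' @return Smoothed field, same dimensions as `f`.
#' @export
gaussian_smooth <- function(f, sigma) {
  check_field(f)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive number", call. = FALSE)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  # rows (y direction)
  h <- nrow(f)
  pr <- min(r, h - 1L)
  fp <- f[reflect_pad_index(h, r), , drop = FALSE]
  out <- matrix(0, h, ncol(f))
  for (t in seq_along(k))
    out <- out + k[t] * fp[(t - 1L) + seq_len(h), , drop = FALSE]
  # columns (x direction)
  w <- ncol(f)
  fp <- out[, reflect_pad_index(w, r), drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(k))
    out <- out + k[t] * fp[, (t - 1L) + seq_len(w), drop = FALSE]
  out
}

#' Gradient of a scalar field
#'
#' Central differences in the interior and one-sided differences at the
#' borders (replicate/Neumann handling).  The x component differentiates
#' along columns, the y component along rows.
#'
#' @param f Scalar field.
#' @return List with fields `x` and `y`, the partial derivatives.
#' @export
field_gradient <- function(f) {
  h <- nrow(f); w <- ncol(f)
  cp <- pmin(seq_len(w) + 1L, w); cm <- pmax(seq_len(w) - 1L, 1L)
  rp <- pmin(seq_len(h) + 1L, h); rm <- pmax(seq_len(h) - 1L, 1L)
  fx <- sweep(f[, cp, drop = FALSE] - f[, cm, drop = FALSE], 2, cp - cm, "/")
  fy <- (f[rp, , drop = FALSE] - f[rm, , drop = FALSE]) / (rp - rm)
  list(x = fx, y = fy)
}

#' Divergence of a vector field
#'
#' @param vx,vy Component fields (numeric matrices of equal dimension).
#' @return `d(vx)/dx + d(vy)/dy` with the same stencil as [field_gradient()].
#' @export
divergence <- function(vx, vy) {
  field_gradient(vx)$x + field_gradient(vy)$y
}

#' Mean curvature of the level lines of a field
#'
#' Computed as `div(grad(f) / |grad(f)|)` with the gradient magnitude floored
#' by `stabilizer` so the result is finite everywhere (flat regions give 0).
#' On a signed distance function of a circle of radius `r` the interior values
#' near the zero level approximate `1/r`.
#'
#' @param f Scalar field.
#' @param stabilizer Small positive value added to the gradient magnitude.
#' @return Curvature field.
#' @export
curvature <- function(f, stabilizer = 1e-10) {
  g <- field_gradient(f)
  nrm <- sqrt(g$x^2 + g$y^2) + stabilizer
  divergence(g$x / nrm, g$y / nrm)
}

#' Smoothed Heaviside step
#'
#' The C1 regularization used to restrict energy terms to a band of width
#' `2*epsilon` around the zero level:
#' `H(x) = (1 + x/eps + sin(pi*x/eps)/pi)/2` for `|x| <= eps`, 0 below the
#' band and 1 above it.  Its derivative on the band is [dirac_smooth()].
#'
#' @param x Numeric vector or matrix.
#' @param epsilon Regularization width; must be positive.
#' @return Values in `[0, 1]`, same shape as `x`.
#' @export
heaviside_smooth <- function(x, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive number", call. = FALSE)
  out <- 0.5 * (1 + x / epsilon + sin(pi * x / epsilon) / pi)
  out[x > epsilon] <- 1
  out[x < -epsilon] <- 0
  out
}

#' Smoothed Dirac delta
#'
#' `d(x) = (1 + cos(pi*x/eps)) / (2*eps)` for `|x| <= eps`, 0 outside; the
#' derivative of [heaviside_smooth()] on the band, with unit integral over the
#' real line.
#'
#' @inheritParams heaviside_smooth
#' @return Nonnegative values, same shape as `x`.
#' @export
dirac_smooth <- function(x, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive number", call. = FALSE)
  out <- (1 + cos(pi * x / epsilon)) / (2 * epsilon)
  out[abs(x) > epsilon] <- 0
  out
}

# Distance to the nearest TRUE pixel, two-pass 3-4-style chamfer with weights
# (1, sqrt(2)).  Accurate to a few percent, which is all the callers need.
chamfer_distance <- function(sites) {
  h <- nrow(sites); w <- ncol(sites)
  big <- (h + w) * 2
  d <- matrix(big, h, w)
  d[sites] <- 0
  s2 <- sqrt(2)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      v <- d[r, c]
      if (c > 1) v <- min(v, d[r, c - 1] + 1)
      if (r > 1) {
        v <- min(v, d[r - 1, c] + 1)
        if (c > 1) v <- min(v, d[r - 1, c - 1] + s2)
        if (c < w) v <- min(v, d[r - 1, c + 1] + s2)
      }
      d[r, c] <- v
    }
  }
  for (r in seq(h, 1)) {
    for (c in seq(w, 1)) {
      v <- d[r, c]
      if (c < w) v <- min(v, d[r, c + 1] + 1)
      if (r < h) {
        v <- min(v, d[r + 1, c] + 1)
        if (c < w) v <- min(v, d[r + 1, c + 1] + s2)
        if (c > 1) v <- min(v, d[r + 1, c - 1] + s2)
      }
      d[r, c] <- v
    }
  }
  d
}

#' Approximate signed distance function of a binary mask
#'
#' Chamfer distance transform, negative inside the mask and positive outside.
#'
#' @param mask Logical matrix.
#' @return Numeric matrix of signed distances in pixels.
#' @export
mask_sdf <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask) || all(mask))
    stop("mask must contain both TRUE and FALSE pixels", call. = FALSE)
  chamfer_distance(mask) - chamfer_distance(!mask)
}
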