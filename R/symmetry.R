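# Symmetry-axis detection and the reflection-symmetry constraint.
#
# The axis of a bilaterally symmetric target is the line through two
# automatically detected points: the centre of gravity of the edge-probability
# mass (which must lie on the axis of a symmetric figure) and the "tip" pole
# of the shape, found as the mean of Harris-corner candidates in a lower
# mid-image search band.  Reflection across the axis is a 3x3 homogeneous
# matrix; reflected fields are resampled bilinearly.

#' Centre of gravity of an edge-probability map
#'
#' Intensity-weighted mean pixel position `(sum(p*x)/sum(p), sum(p*y)/sum(p))`
#' in zero-based coordinates.
#'
#' @param edges Edge-probability map (nonnegative scalar field).
#' @return Numeric `c(x, y)`.
#' @export
edge_centroid <- function(edges) {
  check_field(edges, "edges")
  s <- sum(edges)
  if (s <= 0) stop("edge map has no positive mass", call. = FALSE)
  gr <- coord_grids(dim(edges))
  c(x = sum(edges * gr$x) / s, y = sum(edges * gr$y) / s)
}

#' Harris corner-detection parameters
#'
#' @param window_sigma Gaussian window of the structure tensor, pixels.
#' @param sensitivity The classic Harris `k` in `det - k * trace^2`;
#'   must lie in `[0.01, 0.25]`.
#' @param response_threshold Candidate threshold as a fraction of the maximum
#'   response.
#' @param search_halfwidth Half-width of the tip search strip either side of
#'   the image mid-column, in pixels; `NULL` means 10 percent of the width.
#' @param y_band Fraction of the image height, measured from the bottom, in
#'   which tip candidates are accepted.
#' @return Object of class `harris_params`.
#' @export
harris_params <- function(window_sigma = 2, sensitivity = 0.05,
                          response_threshold = 0.1,
                          search_halfwidth = NULL, y_band = 0.4) {
  if (sensitivity < 0.01 || sensitivity > 0.25)
    stop("sensitivity must lie in [0.01, 0.25]", call. = FALSE)
  if (!is.null(search_halfwidth) && search_halfwidth < 1)
    stop("search_halfwidth must be at least 1 pixel", call. = FALSE)
  structure(list(window_sigma = window_sigma, sensitivity = sensitivity,
                 response_threshold = response_threshold,
                 search_halfwidth = search_halfwidth, y_band = y_band),
            class = "harris_params")
}

#' Harris corner response
#'
#' `det(S) - k * trace(S)^2` of the Gaussian-windowed structure tensor `S` of
#' the image gradients.  Flat regions give 0 and straight edges give
#' non-positive responses; only two-directional intensity change scores high.
#'
#' @param image Scalar field.
#' @param params A [harris_params()] object.
#' @return Response field, same dimensions as `image`.
#' @export
harris_response <- function(image, params = harris_params()) {
  check_field(image, "image")
  g <- field_gradient(image)
  sxx <- gaussian_smooth(g$x * g$x, params$window_sigma)
  syy <- gaussian_smooth(g$y * g$y, params$window_sigma)
  sxy <- gaussian_smooth(g$x * g$y, params$window_sigma)
  (sxx * syy - sxy^2) - params$sensitivity * (sxx + syy)^2
}

#' Detect the tip pole from Harris candidates
#'
#' Candidates are pixels whose response exceeds
#' `response_threshold * max(response)` inside the vertical strip around the
#' image mid-column and the lower `y_band` fraction of the image; the tip is
#' their mean coordinate.
#'
#' @param edges Edge-probability map (used only for shape here; the fallback
#'   in [detect_axis()] consumes it).
#' @param response Harris response field from [harris_response()].
#' @param params A [harris_params()] object.
#' @return Numeric `c(x, y)`; errors with class `symseg_tip_error` when no
#'   candidate survives.
#' @export
detect_tip <- function(edges, response, params = harris_params()) {
  h <- nrow(response); w <- ncol(response)
  halfw <- if (is.null(params$search_halfwidth)) 0.1 * w else params$search_halfwidth
  mid <- (w - 1) / 2
  gr <- coord_grids(c(h, w))
  band <- abs(gr$x - mid) <= halfw & gr$y >= (1 - params$y_band) * (h - 1)
  thr <- params$response_threshold * max(response)
  cand <- band & response >= thr & response > 0
  if (!any(cand))
    stop(structure(class = c("symseg_tip_error", "error", "condition"),
                   list(message = "no corner candidate in the tip search band",
                        call = NULL)))
  c(x = mean(gr$x[cand]), y = mean(gr$y[cand]))
}

# Fallback when the corner search fails (smooth shapes without a true
# corner): lowest pixel with strong edge evidence inside the mid strip.
tip_fallback <- function(edges, params = harris_params()) {
  h <- nrow(edges); w <- ncol(edges)
  halfw <- if (is.null(params$search_halfwidth)) 0.1 * w else params$search_halfwidth
  mid <- (w - 1) / 2
  gr <- coord_grids(c(h, w))
  strong <- abs(gr$x - mid) <= halfw & edges > 0.5 * max(edges)
  if (!any(strong))
    stop(structure(class = c("symseg_tip_error", "error", "condition"),
                   list(message = "no strong edge pixel in the tip search strip",
                        call = NULL)))
  ymax <- max(gr$y[strong])
  sel <- strong & gr$y == ymax
  c(x = mean(gr$x[sel]), y = ymax)
}

# Clip the infinite line A*x + B*y + C = 0 to the image rectangle
# [0, w-1] x [0, h-1]; returns the two boundary intersection points.
line_rect_clip <- function(A, B, C, shape) {
  h <- shape[1]; w <- shape[2]
  n2 <- A^2 + B^2
  p0 <- c(-A * C, -B * C) / n2       # closest point of the line to the origin
  d <- c(B, -A)                      # direction along the line
  t0 <- -Inf; t1 <- Inf
  lims <- rbind(c(p0[1], d[1], 0, w - 1), c(p0[2], d[2], 0, h - 1))
  for (i in 1:2) {
    p <- lims[i, 1]; q <- lims[i, 2]; lo <- lims[i, 3]; hi <- lims[i, 4]
    if (abs(q) < 1e-12) {
      if (p < lo - 1e-9 || p > hi + 1e-9)
        stop("symmetry axis does not intersect the image", call. = FALSE)
    } else {
      ta <- (lo - p) / q; tb <- (hi - p) / q
      t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 > t1) stop("symmetry axis does not intersect the image", call. = FALSE)
  list(a = p0 + t0 * d, b = p0 + t1 * d)
}

#' Symmetry axis through two points
#'
#' Line coefficients in general form `A*x + B*y + C = 0` with
#' `A = y1 - y2`, `B = x2 - x1`, `C = x1*y2 - x2*y1`, together with the axis
#' midpoint `O`: the midpoint of the two intersections of the line with the
#' image rectangle.
#'
#' @param p1 First defining point `c(x, y)` (typically the edge centroid).
#' @param p2 Second defining point (typically the detected tip).
#' @param shape Image shape `c(height, width)` used for the midpoint.
#' @return Object of class `symmetry_axis` with fields `A`, `B`, `C`,
#'   `centroid`, `tip`, `midpoint`, `shape`.
#' @export
axis_from_points <- function(p1, p2, shape) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (sqrt(sum((p1 - p2)^2)) < 1e-9)
    stop("axis points coincide; cannot define a symmetry axis", call. = FALSE)
  A <- p1[2] - p2[2]
  B <- p2[1] - p1[1]
  C <- p1[1] * p2[2] - p2[1] * p1[2]
  ends <- line_rect_clip(A, B, C, shape)
  structure(list(A = A, B = B, C = C,
                 centroid = c(x = p1[1], y = p1[2]),
                 tip = c(x = p2[1], y = p2[2]),
                 midpoint = c(x = (ends$a[1] + ends$b[1]) / 2,
                              y = (ends$a[2] + ends$b[2]) / 2),
                 shape = as.integer(shape)),
            class = "symmetry_axis")
}

#' Symmetry axis from explicit line coefficients
#'
#' Builds a `symmetry_axis` from `A, B, C` directly (e.g. a user-supplied
#' axis); the stored defining points are the rectangle intersections.
#'
#' @param A,B,C Line coefficients, `(A, B)` not both zero.
#' @param shape Image shape `c(height, width)`.
#' @return Object of class `symmetry_axis`.
#' @export
axis_from_coefficients <- function(A, B, C, shape) {
  if (A == 0 && B == 0) stop("(A, B) must not both be zero", call. = FALSE)
  ends <- line_rect_clip(A, B, C, shape)
  structure(list(A = A, B = B, C = C,
                 centroid = c(x = ends$a[1], y = ends$a[2]),
                 tip = c(x = ends$b[1], y = ends$b[2]),
                 midpoint = c(x = (ends$a[1] + ends$b[1]) / 2,
                              y = (ends$a[2] + ends$b[2]) / 2),
                 shape = as.integer(shape)),
            class = "symmetry_axis")
}

#' @export
print.symmetry_axis <- function(x, ...) {
  cat(sprintf("symmetry axis: %.4g*x + %.4g*y + %.4g = 0\n", x$A, x$B, x$C))
  cat(sprintf("  centroid (%.2f, %.2f), tip (%.2f, %.2f), midpoint O (%.2f, %.2f)\n",
              x$centroid[1], x$centroid[2], x$tip[1], x$tip[2],
              x$midpoint[1], x$midpoint[2]))
  invisible(x)
}

#' Refine a symmetry axis by mirror correlation of the edge support
#'
#' The centre of gravity of an edge map is displaced towards the stronger
#' side when edge strength is one-sidedly attenuated, which tilts the
#' centroid-tip axis.  This refinement keeps the (reliably detected) tip
#' fixed and rotates the axis over a small angular range, scoring each
#' candidate by how much of the binarized edge support lands back on the
#' support after reflection; the best-scoring axis is returned.  Binarizing
#' makes the score insensitive to one-sided attenuation, since only the
#' position of the edge ridge matters, not its height.
#'
#' @param edges Edge-probability map.
#' @param axis Initial `symmetry_axis` (its tip is kept as the pivot).
#' @param half_range Angular search half-range in degrees.
#' @param step Angular step in degrees.
#' @param support_threshold Support = pixels with evidence above this
#'   fraction of the map maximum.
#' @return A `symmetry_axis` through the same tip.
#' @export
refine_axis <- function(edges, axis, half_range = 25, step = 0.5,
                        support_threshold = 0.1) {
  supp <- edges >= support_threshold * max(edges)
  if (!any(supp)) return(axis)
  dist_supp <- chamfer_distance(supp)
  gr <- coord_grids(dim(edges))
  px <- gr$x[supp]; py <- gr$y[supp]
  tip <- axis$tip
  base_angle <- atan2(axis$tip[1] - axis$centroid[1],
                      axis$tip[2] - axis$centroid[2])
  h <- nrow(edges); w <- ncol(edges)
  score_angle <- function(theta) {
    d <- c(sin(theta), cos(theta))
    p2 <- c(tip[1] - d[1], tip[2] - d[2])
    A <- tip[2] - p2[2]; B <- p2[1] - tip[1]
    C <- tip[1] * p2[2] - p2[1] * tip[2]
    n2 <- A^2 + B^2
    # reflect support coordinates across the candidate axis
    rx <- ((B^2 - A^2) * px - 2 * A * B * py - 2 * A * C) / n2
    ry <- (-2 * A * B * px + (A^2 - B^2) * py - 2 * B * C) / n2
    ri <- pmin(pmax(round(ry), 0), h - 1) + 1L
    ci <- pmin(pmax(round(rx), 0), w - 1) + 1L
    inside <- rx >= 0 & rx <= w - 1 & ry >= 0 & ry <= h - 1
    d2 <- dist_supp[cbind(ri, ci)]
    mean(inside & d2 <= 1.5)
  }
  angles <- base_angle + seq(-half_range, half_range, by = step) * pi / 180
  scores <- vapply(angles, score_angle, numeric(1))
  best <- angles[which.max(scores)]
  d <- c(sin(best), cos(best))
  len <- max(sqrt(sum((tip - axis$centroid)^2)), 10)
  axis_from_points(tip - len * d, tip, dim(edges))
}

#' Automatic symmetry-axis detection
#'
#' Pipeline step: centre of gravity of the edge map, tip from the Harris
#' response of the image (falling back to the lowest strong-edge pixel in the
#' mid strip when no corner survives), the line through both, and an
#' optional mirror-correlation refinement of the axis direction about the
#' tip (see [refine_axis()]).
#'
#' @param image Grayscale image field (used for the corner response).
#' @param edges Edge-probability map.
#' @param params A [harris_params()] object.
#' @param refine Refine the axis direction by mirror correlation.
#' @return A `symmetry_axis`.
#' @export
detect_axis <- function(image, edges, params = harris_params(),
                        refine = TRUE) {
  ctr <- edge_centroid(edges)
  tip <- tryCatch(
    detect_tip(edges, harris_response(image, params), params),
    symseg_tip_error = function(e) tip_fallback(edges, params))
  axis <- axis_from_points(ctr, tip, dim(edges))
  if (refine) axis <- refine_axis(edges, axis)
  axis
}

#' Homogeneous reflection matrix across an axis
#'
#' For the line `A*x + B*y + C = 0` the reflection is
#' `M = [[B^2-A^2, -2AB, -2AC], [-2AB, A^2-B^2, -2BC], [0, 0, A^2+B^2]]`
#' divided by `A^2 + B^2`.  `M` is an involution and fixes every point of the
#' axis.
#'
#' @param axis A `symmetry_axis`.
#' @return Object of class `reflection_map` with fields `M` (3x3 matrix) and
#'   `axis`.
#' @export
reflection_matrix <- function(axis) {
  A <- axis$A; B <- axis$B; C <- axis$C
  n2 <- A^2 + B^2
  M <- matrix(c(B^2 - A^2, -2 * A * B, 0,
                -2 * A * B, A^2 - B^2, 0,
                -2 * A * C, -2 * B * C, n2), 3, 3) / n2
  structure(list(M = M, axis = axis), class = "reflection_map")
}

#' Reflect a point across an axis
#'
#' @param m A `reflection_map`.
#' @param p Numeric `c(x, y)` or a 2-column matrix of points.
#' @return Reflected point(s), same shape as `p`.
#' @export
reflect_point <- function(m, p) {
  if (is.matrix(p)) {
    q <- cbind(p, 1) %*% t(m$M)
    q[, 1:2, drop = FALSE]
  } else {
    q <- m$M %*% c(p[1], p[2], 1)
    c(x = q[1], y = q[2])
  }
}

#' Precomputed bilinear resampler for a reflection
#'
#' Reflecting a field requires, for every output pixel, a bilinear sample of
#' the input at the mirrored position.  The sample indices and weights depend
#' only on the axis and the field shape, so they are computed once and reused
#' across evolution iterations.
#'
#' @param m A `reflection_map`.
#' @param shape Field shape `c(height, width)`.
#' @param policy Out-of-bounds policy: `"replicate"` clamps the sample
#'   position to the image rectangle; `"background"` marks the pixel so
#'   [reflect_field()] can substitute a fill value.
#' @return Object of class `reflect_sampler`.
#' @export
reflect_sampler <- function(m, shape, policy = c("replicate", "background")) {
  policy <- match.arg(policy)
  h <- shape[1]; w <- shape[2]
  gr <- coord_grids(shape)
  M <- m$M
  xs <- M[1, 1] * gr$x + M[1, 2] * gr$y + M[1, 3]
  ys <- M[2, 1] * gr$x + M[2, 2] * gr$y + M[2, 3]
  oob <- xs < 0 | xs > (w - 1) | ys < 0 | ys > (h - 1)
  xs <- pmin(pmax(xs, 0), w - 1)
  ys <- pmin(pmax(ys, 0), h - 1)
  c0 <- floor(xs); r0 <- floor(ys)
  tx <- xs - c0; ty <- ys - r0
  c0 <- as.integer(c0); r0 <- as.integer(r0)
  c1 <- pmin(c0 + 1L, w - 1L); r1 <- pmin(r0 + 1L, h - 1L)
  lin <- function(r, c) r + 1L + c * h   # 0-based (r, c) to 1-based linear index
  structure(list(
    shape = as.integer(shape), policy = policy, oob = oob,
    i00 = lin(r0, c0), i01 = lin(r0, c1), i10 = lin(r1, c0), i11 = lin(r1, c1),
    w00 = (1 - ty) * (1 - tx), w01 = (1 - ty) * tx,
    w10 = ty * (1 - tx), w11 = ty * tx), class = "reflect_sampler")
}

#' Reflect a scalar field across an axis
#'
#' `fhat(q) = f(M q)` with bilinear interpolation.  Out-of-bounds mirrored
#' positions follow the sampler policy: replicate the nearest edge value
#' (default) or substitute `fill`.
#'
#' @param f Scalar field.
#' @param m A `reflection_map`; ignored when `sampler` is given.
#' @param sampler Optional precomputed [reflect_sampler()].
#' @param fill Fill value for the `"background"` policy.
#' @return Reflected field, same dimensions as `f`.
#' @export
reflect_field <- function(f, m = NULL, sampler = NULL, fill = 0) {
  if (is.null(sampler)) {
    if (is.null(m)) stop("either m or sampler must be given", call. = FALSE)
    sampler <- reflect_sampler(m, dim(f))
  }
  if (!all(dim(f) == sampler$shape))
    stop("field shape does not match the sampler", call. = FALSE)
  v <- sampler$w00 * f[sampler$i00] + sampler$w01 * f[sampler$i01] +
       sampler$w10 * f[sampler$i10] + sampler$w11 * f[sampler$i11]
  out <- matrix(v, sampler$shape[1], sampler$shape[2])
  if (sampler$policy == "background") out[sampler$oob] <- fill
  out
}

#' Symmetry-detection constraint energy
#'
#' `eta * sum((H(-phi)*g - reflected(H(-phi)*g))^2)` over pixels: the squared
#' mismatch between the edge-weighted inside-indicator of the contour and its
#' mirror image across the axis.  Zero (up to resampling tolerance) when the
#' weighted indicator is symmetric about the axis; grows with asymmetry and
#' scales linearly in `eta`.
#'
#' @param phi Level-set field.
#' @param g Stop-function field (same shape).
#' @param m A `reflection_map`; ignored when `sampler` is given.
#' @param eta Nonnegative constraint weight.
#' @param epsilon Heaviside regularization width.
#' @param sampler Optional precomputed [reflect_sampler()].
#' @return Nonnegative scalar.
#' @export
sct_energy <- function(phi, g, m = NULL, eta = 1, epsilon = 1.5, sampler = NULL) {
  if (eta < 0) stop("eta must be nonnegative", call. = FALSE)
  if (!all(dim(phi) == dim(g))) stop("phi and g shapes differ", call. = FALSE)
  wfield <- heaviside_smooth(-phi, epsilon) * g
  what <- reflect_field(wfield, m, sampler)
  eta * sum((wfield - what)^2)
}
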