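# Shared fixtures: all built in code, no files.

# Circular signed-distance fixture on a 64x64 grid with a vertical symmetry
# axis through x = 31.5 (so mirror positions land exactly on grid points).
sym_fixture <- function() {
  shape <- c(64L, 64L)
  phi <- init_circular_sdf(shape, c(31.5, 31.5), 18)
  axis <- axis_from_points(c(31.5, 0), c(31.5, 63), shape)
  list(shape = shape, phi = phi, axis = axis,
       m = reflection_matrix(axis), g = matrix(1, 64, 64))
}

# Same circle with a rectangular notch forced outside on one side of the
# axis: an asymmetric contour with strictly positive symmetry energy.
notched_fixture <- function() {
  fx <- sym_fixture()
  gr <- coord_grids(fx$shape)
  notch <- gr$x > 38 & gr$x < 52 & abs(gr$y - 31.5) < 7
  phi <- fx$phi
  phi[notch] <- pmax(phi[notch], 2)
  fx$phi_notched <- phi
  fx
}

# Unsigned angle between two axes, degrees.
axis_angle_error <- function(ax, ref) {
  a1 <- atan2(-ax$A, ax$B)
  a2 <- atan2(-ref$A, ref$B)
  e <- abs(a1 - a2) %% pi
  min(e, pi - e) * 180 / pi
}

tip_error <- function(ax, ph) sqrt(sum((ax$tip - ph$apex)^2))
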