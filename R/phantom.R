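# Seeded synthetic phantoms: tongue-like bilaterally symmetric blobs with
# ground-truth masks, apex location, true symmetry axis and ground-truth edge
# maps.  The generator emulates the hard cases of clinical tongue images:
# low boundary contrast, speckle on the blob surface, a median crack along
# the axis, and a one-sided attenuation of edge strength.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Geometry and nuisance parameters of one synthetic phantom.  The blob is
#' mirror-symmetric about its axis: an elliptical cap (rounded top) joined to
#' a straight taper ending in a corner at the apex, so a genuine Harris
#' corner exists at the tip.  All coordinates are zero-based pixels.
#'
#' @param shape `c(height, width)`, default 128 x 128.
#' @param apex Tip position `c(x, y)`; `NULL` centres it horizontally at 84
#'   percent of the height.
#' @param axis_angle Axis tilt in degrees from vertical (positive tilts the
#'   apex towards larger x).
#' @param length Blob length along the axis in pixels; `NULL` means 64
#'   percent of the height.
#' @param halfwidth Maximum half-width in pixels; `NULL` means 30 percent of
#'   the width.
#' @param cap_fraction Fraction of the length occupied by the elliptical cap.
#' @param fg_level,bg_level Foreground/background intensities in `[0, 1]`.
#' @param speckle_density Fraction of foreground pixels perturbed by speckle,
#'   at most 0.2.
#' @param speckle_amplitude Intensity delta of speckle.
#' @param crack_width Width in pixels of a dark median crack along the axis;
#'   0 disables it.
#' @param crack_depth Intensity drop inside the crack.
#' @param weak_side_attenuation Multiplier in `(0, 1]` applied to the edge
#'   strength on one side of the axis (1 = symmetric edges).
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param feather_sigma Gaussian feather applied to the mask to build the
#'   image, pixels.
#' @param seed Integer seed; the phantom is bit-identical for a fixed spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L), apex = NULL, axis_angle = 0,
                         length = NULL, halfwidth = NULL, cap_fraction = 0.62,
                         fg_level = 0.85, bg_level = 0.30,
                         speckle_density = 0, speckle_amplitude = 0.25,
                         crack_width = 0, crack_depth = 0.3,
                         weak_side_attenuation = 1, noise_sigma = 0,
                         feather_sigma = 1.2, seed = 1L) {
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  if (is.null(apex)) apex <- c((w - 1) / 2, 0.84 * (h - 1))
  if (is.null(length)) length <- 0.64 * (h - 1)
  if (is.null(halfwidth)) halfwidth <- 0.30 * (w - 1)
  if (apex[1] < 0 || apex[1] > w - 1 || apex[2] < 0 || apex[2] > h - 1)
    stop("apex lies outside the image", call. = FALSE)
  if (fg_level < 0 || fg_level > 1 || bg_level < 0 || bg_level > 1)
    stop("fg_level and bg_level must lie in [0, 1]", call. = FALSE)
  if (speckle_density < 0 || speckle_density > 0.2)
    stop("speckle_density must lie in [0, 0.2]", call. = FALSE)
  if (weak_side_attenuation <= 0 || weak_side_attenuation > 1)
    stop("weak_side_attenuation must lie in (0, 1]", call. = FALSE)
  structure(list(shape = c(h, w), apex = as.numeric(apex),
                 axis_angle = axis_angle, length = length,
                 halfwidth = halfwidth, cap_fraction = cap_fraction,
                 fg_level = fg_level, bg_level = bg_level,
                 speckle_density = speckle_density,
                 speckle_amplitude = speckle_amplitude,
                 crack_width = crack_width, crack_depth = crack_depth,
                 weak_side_attenuation = weak_side_attenuation,
                 noise_sigma = noise_sigma, feather_sigma = feather_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one phantom
#'
#' Builds the mirror-symmetric ground-truth mask, the intensity image
#' (background plus feathered foreground, speckle, crack and noise), the
#' ground-truth edge map (one-pixel mask boundary, Gaussian-feathered,
#' normalized to maximum 1, then attenuated on the weak side), the true
#' symmetry axis and the apex.  Deterministic in the seed.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom`: `image`, `mask` (logical), `apex`,
#'   `axis` (a `symmetry_axis`), `edges` (source `"ground-truth-synthetic"`),
#'   `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$shape[1]; w <- spec$shape[2]
  th <- spec$axis_angle * pi / 180
  d <- c(sin(th), cos(th))            # unit vector root -> apex (y grows down)
  dperp <- c(d[2], -d[1])
  root <- spec$apex - spec$length * d
  gr <- coord_grids(c(h, w))
  relx <- gr$x - root[1]; rely <- gr$y - root[2]
  u <- relx * d[1] + rely * d[2]      # along-axis coordinate, 0 at root
  s <- relx * dperp[1] + rely * dperp[2]   # signed across-axis coordinate
  u0 <- spec$cap_fraction * spec$length
  W <- spec$halfwidth; L <- spec$length
  cap <- u >= 0 & u <= u0 &
    ((s / W)^2 + ((u - u0) / u0)^2) <= 1
  taper <- u > u0 & u <= L & abs(s) <= W * (L - u) / (L - u0)
  mask <- cap | taper

  soft <- gaussian_smooth(mask + 0, spec$feather_sigma)
  image <- spec$bg_level + (spec$fg_level - spec$bg_level) * soft

  if (spec$crack_width > 0) {
    crack <- abs(s) <= spec$crack_width / 2 & u >= 0.25 * L & u <= 0.85 * L & mask
    image <- image - spec$crack_depth *
      gaussian_smooth(crack + 0, 0.8)
  }

  image <- with_local_seed(spec$seed, {
    if (spec$speckle_density > 0) {
      fg_idx <- which(mask)
      n_sp <- round(spec$speckle_density * length(fg_idx))
      if (n_sp > 0) {
        idx <- sample(fg_idx, n_sp)
        image[idx] <- image[idx] +
          sample(c(-1, 1), n_sp, replace = TRUE) * spec$speckle_amplitude
      }
    }
    if (spec$noise_sigma > 0)
      image <- image + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
    image
  })
  image <- pmin(pmax(image, 0), 1)

  # edge ridge centred on the mask interface: the union of the inner
  # boundary (erosion residue) and outer boundary (dilation residue), so the
  # feathered ridge peaks on the true region boundary rather than half a
  # pixel inside it
  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  core <- pad[2:(h + 1), 2:(w + 1)] & pad[1:h, 2:(w + 1)] &
    pad[3:(h + 2), 2:(w + 1)] & pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  halo <- pad[2:(h + 1), 2:(w + 1)] | pad[1:h, 2:(w + 1)] |
    pad[3:(h + 2), 2:(w + 1)] | pad[2:(h + 1), 1:w] | pad[2:(h + 1), 3:(w + 2)]
  boundary <- (mask & !core) | (halo & !mask)
  edges <- gaussian_smooth(boundary + 0, 1)
  mx <- max(edges)
  if (mx > 0) edges <- edges / mx
  if (spec$weak_side_attenuation < 1)
    edges[s > 0] <- edges[s > 0] * spec$weak_side_attenuation

  axis <- axis_from_points(root, spec$apex, c(h, w))
  structure(list(image = image, mask = mask, apex = spec$apex, axis = axis,
                 edges = edge_map(edges, "ground-truth-synthetic"),
                 spec = spec),
            class = "phantom")
}

#' Disk phantom
#'
#' A high-contrast disk on a flat background with its ground-truth mask and
#' edge map; the simplest target for exercising the plain DRLSE flow.
#'
#' @param shape `c(height, width)`.
#' @param center Disk centre `c(x, y)`; `NULL` means the image centre.
#' @param radius Disk radius in pixels.
#' @param fg_level,bg_level Intensities.
#' @param noise_sigma Additive Gaussian noise.
#' @param seed Integer seed for the noise.
#' @return List of class `phantom` (axis: the vertical line through the
#'   centre; apex: the lowest disk point).
#' @export
disk_phantom <- function(shape = c(128L, 128L), center = NULL, radius = 35,
                         fg_level = 0.9, bg_level = 0.2, noise_sigma = 0,
                         seed = 1L) {
  h <- shape[1]; w <- shape[2]
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  gr <- coord_grids(shape)
  rr <- sqrt((gr$x - center[1])^2 + (gr$y - center[2])^2)
  mask <- rr <= radius
  soft <- gaussian_smooth(mask + 0, 1.2)
  image <- bg_level + (fg_level - bg_level) * soft
  if (noise_sigma > 0)
    image <- with_local_seed(seed, image +
      matrix(stats::rnorm(h * w, 0, noise_sigma), h, w))
  image <- pmin(pmax(image, 0), 1)
  band <- abs(rr - radius) <= 0.5
  edges <- gaussian_smooth(band + 0, 1)
  edges <- edges / max(edges)
  axis <- axis_from_points(center, center + c(0, radius), shape)
  structure(list(image = image, mask = mask,
                 apex = c(center[1], center[2] + radius), axis = axis,
                 edges = edge_map(edges, "ground-truth-synthetic"),
                 spec = list(shape = shape, seed = seed)),
            class = "phantom")
}

phantom_presets <- c("clean", "low-contrast", "speckle", "crack", "weak-side")

preset_spec <- function(preset, seed) {
  jit <- function(lo, hi) stats::runif(1, lo, hi)
  with_local_seed(seed, {
    h <- 128L; w <- 128L
    base <- list(
      shape = c(h, w),
      apex = c((w - 1) / 2 + jit(-3, 3), 0.84 * (h - 1) + jit(-3, 3)),
      axis_angle = jit(-3, 3),
      length = 0.64 * (h - 1) * jit(0.96, 1.04),
      halfwidth = 0.30 * (w - 1) * jit(0.9, 1.1),
      seed = seed)
    extra <- switch(preset,
      "clean" = list(fg_level = 0.85, bg_level = 0.30),
      "low-contrast" = list(fg_level = 0.52, bg_level = 0.44,
                            noise_sigma = 0.01),
      "speckle" = list(speckle_density = 0.1, speckle_amplitude = 0.25,
                       noise_sigma = 0.01),
      "crack" = list(crack_width = 3, crack_depth = 0.3, noise_sigma = 0.01),
      "weak-side" = list(weak_side_attenuation = 0.2),
      stop("unknown preset: ", preset, call. = FALSE))
    do.call(phantom_spec, c(base, extra))
  })
}

#' Generate a suite of phantoms
#'
#' `n` phantoms drawn from a named preset with mild per-item variation of
#' apex position, axis tilt, size and (per preset) nuisance parameters.
#' Item seeds are derived deterministically from `seed`, so the suite is
#' reproducible.
#'
#' @param preset One of `"clean"`, `"low-contrast"`, `"speckle"`, `"crack"`,
#'   `"weak-side"`.
#' @param n Number of phantoms, at least 1.
#' @param seed Base integer seed.
#' @return List of `n` `phantom` objects.
#' @export
phantom_suite <- function(preset = "clean", n = 1, seed = 1L) {
  preset <- match.arg(preset, phantom_presets)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  lapply(seq_len(n), function(i)
    generate_phantom(preset_spec(preset, as.integer(seed) + 7919L * i)))
}

#' Write a phantom to disk
#'
#' Emits `<prefix>_image.png`, `<prefix>_mask.png` (0/255),
#' `<prefix>_edges.png` (8-bit), a lossless float sidecar
#' `<prefix>_image_f32.tiff`, and a plain-text YAML manifest
#' `<prefix>_manifest.yaml` with the spec fields, seed, apex and axis.
#'
#' @param ph A `phantom`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; `NULL` uses `phantom_seed<seed>`.
#' @return Character vector of the written paths, invisibly.
#' @export
write_phantom <- function(ph, dir, prefix = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(prefix)) prefix <- sprintf("phantom_seed%d", ph$spec$seed)
  paths <- file.path(dir, paste0(prefix, c("_image.png", "_mask.png",
                                           "_edges.png", "_image_f32.tiff",
                                           "_manifest.yaml")))
  write_image(ph$image, paths[1])
  write_image(ph$mask + 0, paths[2])
  write_image(ph$edges, paths[3])
  tiff::writeTIFF(ph$image, paths[4], bits.per.sample = 32L,
                  compression = "none", reduce = TRUE)
  manifest <- c(unclass(ph$spec)[setdiff(names(ph$spec), c("shape", "apex"))],
                list(shape = as.integer(ph$spec$shape),
                     apex = as.numeric(ph$apex),
                     axis = as.numeric(c(ph$axis$A, ph$axis$B, ph$axis$C))))
  yaml::write_yaml(manifest, paths[5])
  invisible(paths)
}
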