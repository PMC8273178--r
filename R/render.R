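# Stimulus renderers: patch patterns, background/mask textures and enveloped
# gratings. All renderers are pure functions of (spec, seed, geometry);
# every random draw goes through a locally seeded RNG.

#' Texture specification
#'
#' The achromatic textures of both experiments: the background of randomly
#' placed and oriented ellipses (fMRI experiment) and the mask tiling of
#' axis-aligned squares (psychophysics). Element luminances are drawn from
#' exactly eight levels; the embedded defaults span the printed ranges with
#' equal spacing.
#'
#' @param element_shape `"ellipse"` or `"square"`.
#' @param element_size_deg Length-2 numeric, element size in degrees
#'   (defaults: ellipse 3.3 x 1.8, square 1.5 x 1.5).
#' @param n_elements Number of elements (600 for the ellipse background;
#'   ignored for squares, which tile the region completely).
#' @param luminance_levels Exactly eight luminances in cd/m2.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(element_shape = c("ellipse", "square"),
                         element_size_deg = NULL,
                         n_elements = 600,
                         luminance_levels = NULL) {
  element_shape <- match.arg(element_shape)
  if (is.null(element_size_deg)) {
    element_size_deg <- if (element_shape == "ellipse") c(3.3, 1.8) else c(1.5, 1.5)
  }
  if (is.null(luminance_levels)) {
    luminance_levels <- if (element_shape == "ellipse") {
      seq(0.23, 30.24, length.out = 8)
    } else {
      seq(0.32, 30.37, length.out = 8)
    }
  }
  if (length(luminance_levels) != 8L) {
    stop("exactly 8 luminance levels are required, got ",
      length(luminance_levels),
      call. = FALSE
    )
  }
  structure(
    list(
      element_shape = element_shape,
      element_size_deg = element_size_deg,
      n_elements = as.integer(n_elements),
      luminance_levels = as.numeric(luminance_levels)
    ),
    class = "texture_spec"
  )
}

#' Render an achromatic texture
#'
#' Ellipse textures place `n_elements` ellipses at seeded uniform positions
#' and orientations, each filled with one of the eight luminance levels;
#' pixels left uncovered take the fourth (mid) level so every texture pixel
#' carries one of the eight levels. Square textures tile the region with
#' axis-aligned squares of independently drawn levels.
#'
#' @param spec A [texture_spec()].
#' @param seed Integer seed.
#' @param geometry A [display_geometry()].
#' @param region Optional logical matrix; pixels outside it are left at
#'   `black_luminance`.
#' @param black_luminance Luminance outside `region`, cd/m2.
#' @return A [stimulus_image()].
#' @export
render_texture <- function(spec, seed, geometry = fmri_display(),
                           region = NULL, black_luminance = 0.05) {
  stopifnot(inherits(spec, "texture_spec"))
  nx <- geometry$width_px
  ny <- geometry$height_px
  levels <- spec$luminance_levels
  lum <- matrix(black_luminance, ny, nx)
  in_region <- if (is.null(region)) matrix(TRUE, ny, nx) else region
  if (spec$element_shape == "ellipse") {
    base <- levels[4L]
    lum[in_region] <- base
    a <- spec$element_size_deg[1] / 2
    b <- spec$element_size_deg[2] / 2
    n <- spec$n_elements
    draws <- with_seed(seed, list(
      cx = stats::runif(n, -geometry$width_deg / 2, geometry$width_deg / 2),
      cy = stats::runif(n, -geometry$height_deg / 2, geometry$height_deg / 2),
      theta = stats::runif(n, 0, pi),
      lev = sample.int(8L, n, replace = TRUE)
    ))
    for (i in seq_len(n)) {
      lum <- paint_ellipse(
        lum, geometry, draws$cx[i], draws$cy[i], a, b,
        draws$theta[i], levels[draws$lev[i]], in_region
      )
    }
  } else {
    side <- spec$element_size_deg[1]
    sx <- nx / geometry$width_deg
    sy <- ny / geometry$height_deg
    tx <- pmin(floor((seq_len(nx) - 0.5) / (side * sx)), 1e6) + 1L
    ty <- pmin(floor((seq_len(ny) - 0.5) / (side * sy)), 1e6) + 1L
    ntx <- max(tx)
    nty <- max(ty)
    tile_lev <- with_seed(
      seed,
      matrix(sample.int(8L, ntx * nty, replace = TRUE), nty, ntx)
    )
    full <- matrix(levels[tile_lev[cbind(
      rep(ty, times = nx), rep(tx, each = ny)
    )]], ny, nx)
    lum[in_region] <- full[in_region]
  }
  stimulus_image(lum,
    geometry = geometry,
    provenance = list(kind = "texture", spec = unclass(spec), seed = seed)
  )
}

# Fill a rotated ellipse (semi-axes a, b in deg, orientation theta) with a
# luminance value, restricted to in_region pixels.
paint_ellipse <- function(lum, geometry, cx, cy, a, b, theta, value,
                          in_region) {
  nx <- geometry$width_px
  ny <- geometry$height_px
  sx <- nx / geometry$width_deg
  sy <- ny / geometry$height_deg
  r <- max(a, b)
  c0 <- max(1L, floor((cx - r) * sx + nx / 2) + 1L)
  c1 <- min(nx, ceiling((cx + r) * sx + nx / 2))
  r0 <- max(1L, floor(ny / 2 - (cy + r) * sy) + 1L)
  r1 <- min(ny, ceiling(ny / 2 - (cy - r) * sy))
  if (c0 > c1 || r0 > r1) {
    return(lum)
  }
  cols <- c0:c1
  rows <- r0:r1
  xd <- ((cols - 0.5) - nx / 2) / sx - cx
  yd <- (ny / 2 - (rows - 0.5)) / sy - cy
  dx <- matrix(xd, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(yd, length(rows), length(cols))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  sub <- lum[rows, cols, drop = FALSE]
  sub[inside & in_region[rows, cols]] <- value
  lum[rows, cols] <- sub
  lum
}

# Indices (into the full matrix) of a disk of given radius (deg) at (cx, cy).
disk_index <- function(geometry, cx, cy, radius) {
  nx <- geometry$width_px
  ny <- geometry$height_px
  sx <- nx / geometry$width_deg
  sy <- ny / geometry$height_deg
  c0 <- max(1L, floor((cx - radius) * sx + nx / 2) + 1L)
  c1 <- min(nx, ceiling((cx + radius) * sx + nx / 2))
  r0 <- max(1L, floor(ny / 2 - (cy + radius) * sy) + 1L)
  r1 <- min(ny, ceiling(ny / 2 - (cy - radius) * sy))
  if (c0 > c1 || r0 > r1) {
    return(integer(0))
  }
  cols <- c0:c1
  rows <- r0:r1
  xd <- ((cols - 0.5) - nx / 2) / sx - cx
  yd <- (ny / 2 - (rows - 0.5)) / sy - cy
  dx <- matrix(xd, length(rows), length(cols), byrow = TRUE)
  dy <- matrix(yd, length(rows), length(cols))
  inside <- dx * dx + dy * dy <= radius^2
  idx <- outer(rows, (cols - 1L) * ny, `+`)
  idx[inside]
}

#' Patch-pattern specification
#'
#' Ten colored patches on a ring: patch centers sit on a 12.4 deg diameter
#' circle at equal 36 deg polar-angle steps, each patch a 3.0 deg disk with a
#' 15 arcmin black fringe, over either the ellipse-texture background (main
#' experiment) or a uniformly black background (control experiment). The
#' whole ring is jittered by one of -12/0/+12 deg per presentation.
#'
#' @param chroma_condition `"/0"`, `"/2"`, `"/4"` or `"/6"`.
#' @param background `"texture"` or `"black"`.
#' @param n_patches,circle_diameter_deg,patch_diameter_deg Ring geometry.
#' @param fringe_width_arcmin Black fringe width in arcmin.
#' @param rotation_jitter_deg Candidate whole-ring rotations, degrees.
#' @param value5_luminance Luminance of the Value-5 chips, cd/m2.
#' @param fixation_size_deg Side of the central white fixation rectangle.
#' @param fixation_luminance Fixation luminance; defaults to the display
#'   white implied by `value5_luminance`.
#' @return An object of class `patch_pattern_spec`.
#' @export
patch_pattern_spec <- function(chroma_condition = "/0",
                               background = c("texture", "black"),
                               n_patches = 10L,
                               circle_diameter_deg = 12.4,
                               patch_diameter_deg = 3.0,
                               fringe_width_arcmin = 15,
                               rotation_jitter_deg = c(-12, 0, 12),
                               value5_luminance = 16.0,
                               fixation_size_deg = 0.3,
                               fixation_luminance = NULL) {
  check_chroma(chroma_condition)
  background <- match.arg(background)
  if (is.null(fixation_luminance)) {
    fixation_luminance <- white_for_value5(value5_luminance)
  }
  structure(
    list(
      chroma_condition = chroma_condition, background = background,
      n_patches = as.integer(n_patches),
      circle_diameter_deg = circle_diameter_deg,
      patch_diameter_deg = patch_diameter_deg,
      fringe_width_arcmin = fringe_width_arcmin,
      rotation_jitter_deg = rotation_jitter_deg,
      value5_luminance = value5_luminance,
      fixation_size_deg = fixation_size_deg,
      fixation_luminance = fixation_luminance
    ),
    class = "patch_pattern_spec"
  )
}

# Ring geometry shared by the patch pattern and the grating overlay.
# Returns centers (deg), radii and the seeded jitter / hue arrangement.
ring_layout <- function(spec, seed) {
  s_arr <- derive_seed(seed, 2L)
  s_jit <- derive_seed(seed, 3L)
  jitter <- with_seed(s_jit, sample(spec$rotation_jitter_deg, 1L))
  arrangement <- with_seed(s_arr, sample.int(spec$n_patches))
  k <- seq_len(spec$n_patches) - 1L
  ang <- (90 + jitter - k * 360 / spec$n_patches) * pi / 180
  r <- spec$circle_diameter_deg / 2
  list(
    cx = r * cos(ang), cy = r * sin(ang),
    jitter = jitter, arrangement = arrangement,
    patch_radius = spec$patch_diameter_deg / 2,
    fringe_radius = spec$patch_diameter_deg / 2 +
      spec$fringe_width_arcmin / 60
  )
}

# Stamp patches (black fringe annulus + colored disk) onto luminance and
# chromaticity planes; returns the planes plus the patch-region indices.
stamp_patches <- function(lum, cx_plane, cy_plane, geometry, layout, chips,
                          patch_luminance, black_luminance = 0.05) {
  patch_idx <- integer(0)
  for (k in seq_along(layout$cx)) {
    chip <- chips[layout$arrangement[k], ]
    ring_idx <- disk_index(
      geometry, layout$cx[k], layout$cy[k],
      layout$fringe_radius
    )
    core_idx <- disk_index(
      geometry, layout$cx[k], layout$cy[k],
      layout$patch_radius
    )
    lum[ring_idx] <- black_luminance
    w <- d65_white()
    cx_plane[ring_idx] <- w[["x"]]
    cy_plane[ring_idx] <- w[["y"]]
    lum[core_idx] <- patch_luminance
    cx_plane[core_idx] <- chip$x
    cy_plane[core_idx] <- chip$y
    patch_idx <- c(patch_idx, ring_idx)
  }
  list(lum = lum, cx = cx_plane, cy = cy_plane, patch_idx = patch_idx)
}

#' Render the patch pattern
#'
#' Draws the ten-patch ring (hue arrangement permuted per seed, ring rotation
#' jittered per seed by one of -12/0/+12 deg) over the requested background,
#' with a white fixation rectangle at the center. The returned image records
#' the fixation and patch pixel sets in its provenance for
#' [scramble_stimulus()].
#'
#' @param spec A [patch_pattern_spec()].
#' @param seed Integer seed (controls background texture, hue arrangement and
#'   ring jitter).
#' @param geometry A [display_geometry()].
#' @return A [stimulus_image()].
#' @export
#' @examples
#' geom <- display_geometry(69, 31.5, 25.2, 160, 128)
#' img <- render_patch_pattern(patch_pattern_spec("/6"), seed = 1, geom)
render_patch_pattern <- function(spec, seed, geometry = fmri_display()) {
  stopifnot(inherits(spec, "patch_pattern_spec"))
  layout <- ring_layout(spec, seed)
  extent <- spec$circle_diameter_deg / 2 + layout$fringe_radius
  if (extent > min(geometry$width_deg, geometry$height_deg) / 2) {
    stop("patch geometry exceeds screen bounds", call. = FALSE)
  }
  nx <- geometry$width_px
  ny <- geometry$height_px
  if (spec$background == "texture") {
    bg <- render_texture(texture_spec("ellipse"), derive_seed(seed, 1L),
      geometry
    )
    lum <- bg$luminance
  } else {
    lum <- matrix(0.05, ny, nx)
  }
  w <- d65_white()
  cx_plane <- matrix(w[["x"]], ny, nx)
  cy_plane <- matrix(w[["y"]], ny, nx)
  chips <- chip_set(spec$chroma_condition,
    white_luminance = white_for_value5(spec$value5_luminance)
  )
  st <- stamp_patches(
    lum, cx_plane, cy_plane, geometry, layout, chips,
    patch_luminance = spec$value5_luminance
  )
  fix_idx <- fixation_index(geometry, spec$fixation_size_deg)
  st$lum[fix_idx] <- spec$fixation_luminance
  st$cx[fix_idx] <- w[["x"]]
  st$cy[fix_idx] <- w[["y"]]
  stimulus_image(st$lum, st$cx, st$cy, geometry,
    provenance = list(
      kind = "patch_pattern", spec = unclass(spec), seed = seed,
      jitter_deg = layout$jitter, arrangement = layout$arrangement,
      patch_centers_deg = list(x = layout$cx, y = layout$cy),
      fixation_idx = fix_idx, patch_idx = st$patch_idx
    )
  )
}

fixation_index <- function(geometry, size_deg) {
  nx <- geometry$width_px
  ny <- geometry$height_px
  sx <- nx / geometry$width_deg
  sy <- ny / geometry$height_deg
  half <- size_deg / 2
  cols <- max(1L, floor(nx / 2 - half * sx) + 1L):min(nx, ceiling(nx / 2 + half * sx))
  rows <- max(1L, floor(ny / 2 - half * sy) + 1L):min(ny, ceiling(ny / 2 + half * sy))
  as.integer(outer(rows, (cols - 1L) * ny, `+`))
}

#' Grating specification
#'
#' The psychophysical stimulus: a vertical achromatic grating whose contrast
#' declines exponentially with eccentricity (1/e at 3.75 deg), with the
#' cosine phase fixed so that the screen center is a luminance trough
#' (negative contrast at the center), and the ten-patch ring overlaid
#' opaquely on top.
#'
#' @param contrast Maximum (carrier) Michelson contrast, in `[0, 1)`;
#'   reference stimuli use 0.50, test stimuli 0.34-0.66.
#' @param chroma_condition Chroma of the overlaid patches.
#' @param spatial_frequency_cpd Carrier frequency, cycles/deg.
#' @param envelope_decay_deg Eccentricity of 1/e contrast decline, deg.
#' @param mean_luminance Grating mean and patch luminance, cd/m2.
#' @param overlay_patches Overlay the patch ring (`TRUE` for the experiment's
#'   stimuli; `FALSE` gives the bare grating).
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(contrast = 0.50,
                         chroma_condition = "/0",
                         spatial_frequency_cpd = 0.67,
                         envelope_decay_deg = 3.75,
                         mean_luminance = 19.8,
                         overlay_patches = TRUE) {
  if (!is.finite(contrast) || contrast < 0 || contrast >= 1) {
    stop("contrast must lie in [0, 1)", call. = FALSE)
  }
  check_chroma(chroma_condition)
  structure(
    list(
      contrast = contrast, chroma_condition = chroma_condition,
      spatial_frequency_cpd = spatial_frequency_cpd,
      envelope_decay_deg = envelope_decay_deg,
      mean_luminance = mean_luminance,
      overlay_patches = overlay_patches
    ),
    class = "grating_spec"
  )
}

#' Render the enveloped grating with patch overlay
#'
#' Luminance outside the overlay is
#' `L(x, y) = Lmean * (1 + C * cos(2 pi f x + pi) * exp(-r / lambda))`
#' with `r` the eccentricity, so the center pixel is the most-modulated point
#' and a trough (`L < Lmean`). Overlaid patches are opaque disks at the
#' patch luminance with black fringes, arranged as in the fMRI experiment.
#'
#' @param spec A [grating_spec()].
#' @param seed Integer seed for the overlay arrangement and jitter.
#' @param geometry A [display_geometry()].
#' @return A [stimulus_image()]; provenance records `mean_luminance` and
#'   `grating_idx` (pixels not covered by the overlay).
#' @export
render_grating <- function(spec, seed = 1L, geometry = psycho_display()) {
  stopifnot(inherits(spec, "grating_spec"))
  grid <- pixel_grid(geometry)
  r <- sqrt(grid$x^2 + grid$y^2)
  carrier <- cos(2 * pi * spec$spatial_frequency_cpd * grid$x + pi)
  lum <- spec$mean_luminance *
    (1 + spec$contrast * carrier * exp(-r / spec$envelope_decay_deg))
  w <- d65_white()
  ny <- geometry$height_px
  nx <- geometry$width_px
  cx_plane <- matrix(w[["x"]], ny, nx)
  cy_plane <- matrix(w[["y"]], ny, nx)
  patch_idx <- integer(0)
  layout <- NULL
  if (spec$overlay_patches) {
    pspec <- patch_pattern_spec(spec$chroma_condition,
      background = "black",
      value5_luminance = spec$mean_luminance
    )
    layout <- ring_layout(pspec, seed)
    chips <- chip_set(spec$chroma_condition,
      white_luminance = white_for_value5(spec$mean_luminance)
    )
    st <- stamp_patches(lum, cx_plane, cy_plane, geometry, layout, chips,
      patch_luminance = spec$mean_luminance
    )
    lum <- st$lum
    cx_plane <- st$cx
    cy_plane <- st$cy
    patch_idx <- st$patch_idx
  }
  grating_idx <- setdiff(seq_len(ny * nx), patch_idx)
  stimulus_image(lum, cx_plane, cy_plane, geometry,
    provenance = list(
      kind = "grating", spec = unclass(spec), seed = seed,
      mean_luminance = spec$mean_luminance,
      jitter_deg = if (is.null(layout)) NULL else layout$jitter,
      patch_idx = patch_idx, grating_idx = grating_idx,
      fixation_idx = integer(0)
    )
  )
}
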