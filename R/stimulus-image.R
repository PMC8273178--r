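#' Stimulus image container
#'
#' A rasterized stimulus: per-pixel luminance (cd/m2) plus CIE 1931
#' chromaticity planes, together with the display geometry and the generating
#' spec and seed (provenance). Regenerating with an identical spec and seed
#' is bit-identical.
#'
#' @param luminance Numeric matrix of luminances (cd/m2), rows = y pixels.
#' @param chroma_x,chroma_y Matrices of CIE x and y chromaticities, same
#'   dimension as `luminance`.
#' @param geometry A [display_geometry()].
#' @param provenance List carrying at least `spec` and `seed`; renderers add
#'   pixel masks (fixation, patches) used by [scramble_stimulus()].
#' @return An object of class `stimulus_image`.
#' @export
stimulus_image <- function(luminance, chroma_x = NULL, chroma_y = NULL,
                           geometry, provenance = list()) {
  if (!is.matrix(luminance) || !is.numeric(luminance)) {
    stop("luminance must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(luminance)) || any(luminance < 0)) {
    stop("luminances must be finite and >= 0", call. = FALSE)
  }
  w <- d65_white()
  if (is.null(chroma_x)) {
    chroma_x <- matrix(w["x"], nrow(luminance), ncol(luminance))
  }
  if (is.null(chroma_y)) {
    chroma_y <- matrix(w["y"], nrow(luminance), ncol(luminance))
  }
  if (!identical(dim(chroma_x), dim(luminance)) ||
    !identical(dim(chroma_y), dim(luminance))) {
    stop("chromaticity planes must match the luminance plane", call. = FALSE)
  }
  if (any(chroma_x < 0) || any(chroma_y < 0) ||
    any(chroma_x + chroma_y > 1)) {
    stop("chromaticities must lie inside the CIE 1931 diagram", call. = FALSE)
  }
  stopifnot(
    nrow(luminance) == geometry$height_px,
    ncol(luminance) == geometry$width_px
  )
  structure(
    list(
      luminance = luminance, chroma_x = chroma_x, chroma_y = chroma_y,
      geometry = geometry, provenance = provenance
    ),
    class = "stimulus_image"
  )
}

#' @export
print.stimulus_image <- function(x, ...) {
  cat(sprintf(
    "Stimulus image %d x %d px (%.1f x %.1f deg), luminance %.2f-%.2f cd/m2\n",
    x$geometry$width_px, x$geometry$height_px,
    x$geometry$width_deg, x$geometry$height_deg,
    min(x$luminance), max(x$luminance)
  ))
  if (!is.null(x$provenance$kind)) {
    cat(
      " kind:", x$provenance$kind,
      if (!is.null(x$provenance$seed)) paste0("(seed ", x$provenance$seed, ")"),
      "\n"
    )
  }
  invisible(x)
}

#' Michelson contrast of an image region
#'
#' Two measures are available. `"minmax"` is the plain Michelson quotient
#' `(Lmax - Lmin) / (Lmax + Lmin)` over the region. `"modulation"` is the
#' spatially-maximum modulation contrast `max |L - Lref| / Lref` relative to
#' a reference (mean) luminance: for an enveloped grating this recovers the
#' carrier contrast at the most-modulated point (the central trough), which
#' the plain min-max quotient understates because the nearest crest sits half
#' a period away where the envelope has already decayed.
#'
#' @param image A [stimulus_image()], or a plain numeric matrix/vector of
#'   luminances.
#' @param region Optional logical mask (same shape as the luminance plane) or
#'   index vector selecting the pixels to measure. Default: all pixels.
#' @param method `"minmax"` (default) or `"modulation"`.
#' @param reference_luminance Reference luminance for `"modulation"`;
#'   defaults to the `mean_luminance` recorded in the image provenance, else
#'   the region mean.
#' @return Michelson contrast as a fraction in `[0, 1]` (modulation contrast
#'   can exceed 1 for luminances above twice the reference).
#' @export
#' @examples
#' measure_michelson(c(10, 30)) # 0.5
measure_michelson <- function(image, region = NULL,
                              method = c("minmax", "modulation"),
                              reference_luminance = NULL) {
  method <- match.arg(method)
  lum <- if (inherits(image, "stimulus_image")) image$luminance else image
  vals <- if (is.null(region)) as.numeric(lum) else as.numeric(lum[region])
  if (length(vals) == 0L) stop("empty region", call. = FALSE)
  if (method == "minmax") {
    lo <- min(vals)
    hi <- max(vals)
    if (hi + lo == 0) {
      stop("undefined contrast: region luminances are all zero", call. = FALSE)
    }
    (hi - lo) / (hi + lo)
  } else {
    if (is.null(reference_luminance)) {
      reference_luminance <- if (inherits(image, "stimulus_image") &&
        !is.null(image$provenance$mean_luminance)) {
        image$provenance$mean_luminance
      } else {
        mean(vals)
      }
    }
    if (reference_luminance <= 0) {
      stop("undefined contrast: non-positive reference luminance",
        call. = FALSE
      )
    }
    max(abs(vals - reference_luminance)) / reference_luminance
  }
}

#' Scramble a stimulus by permuting pixel locations
#'
#' Pseudorandomly relocates pixels, preserving the pixel-value multiset. In
#' `"full"` mode every pixel is permuted except protected ones; with
#' `protect_fixation = TRUE` the white fixation rectangle (recorded in the
#' image provenance by the renderer) stays in place. In `"patches_only"` mode
#' only pixels at the patch-disk locations are permuted among themselves and
#' the remainder of the screen is set to black, matching the control
#' experiment's scrambled pattern.
#'
#' @param image A [stimulus_image()] produced by a renderer in this package.
#' @param seed Integer seed for the permutation.
#' @param mode `"full"` or `"patches_only"`.
#' @param protect_fixation Keep the fixation-rectangle pixels unchanged.
#' @param black_luminance Luminance of the blanked area in `"patches_only"`
#'   mode (cd/m2).
#' @return A scrambled [stimulus_image()].
#' @export
scramble_stimulus <- function(image, seed, mode = c("full", "patches_only"),
                              protect_fixation = TRUE,
                              black_luminance = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "stimulus_image"))
  n <- length(image$luminance)
  fix_idx <- image$provenance$fixation_idx
  if (mode == "full") {
    movable <- seq_len(n)
    if (protect_fixation && length(fix_idx)) movable <- setdiff(movable, fix_idx)
    perm <- with_seed(seed, sample(movable))
    lum <- image$luminance
    cx <- image$chroma_x
    cy <- image$chroma_y
    lum[movable] <- image$luminance[perm]
    cx[movable] <- image$chroma_x[perm]
    cy[movable] <- image$chroma_y[perm]
  } else {
    patch_idx <- image$provenance$patch_idx
    if (is.null(patch_idx)) {
      stop("image provenance carries no patch locations; ",
        "render it with render_patch_pattern()",
        call. = FALSE
      )
    }
    w <- d65_white()
    lum <- matrix(black_luminance, nrow(image$luminance), ncol(image$luminance))
    cx <- matrix(w[["x"]], nrow(lum), ncol(lum))
    cy <- matrix(w[["y"]], nrow(lum), ncol(lum))
    perm <- with_seed(seed, sample(patch_idx))
    lum[patch_idx] <- image$luminance[perm]
    cx[patch_idx] <- image$chroma_x[perm]
    cy[patch_idx] <- image$chroma_y[perm]
    if (protect_fixation && length(fix_idx)) {
      lum[fix_idx] <- image$luminance[fix_idx]
      cx[fix_idx] <- image$chroma_x[fix_idx]
      cy[fix_idx] <- image$chroma_y[fix_idx]
    }
  }
  prov <- image$provenance
  prov$scramble <- list(mode = mode, seed = seed,
    protect_fixation = protect_fixation
  )
  stimulus_image(lum, cx, cy, image$geometry, prov)
}

#' Write / read a stimulus image as 16-bit-precision PNG plus a sidecar
#'
#' The luminance plane is stored at 16-bit precision (scaled by the recorded
#' maximum, with the high and low bytes packed into the first two PNG
#' channels, as noted in the sidecar); the chromaticity planes, which are
#' piecewise constant, are stored as a palette plus an 8-bit index PNG;
#' geometry, spec and seed go to a YAML sidecar. `read_stimulus()`
#' reconstructs the image (luminance quantized to 16 bits).
#'
#' @param image A [stimulus_image()].
#' @param prefix Output path prefix; files `<prefix>.png`,
#'   `<prefix>_chroma.png` and `<prefix>.yaml` are written.
#' @return `write_stimulus()` the prefix, invisibly; `read_stimulus()` a
#'   [stimulus_image()].
#' @export
write_stimulus <- function(image, prefix) {
  stopifnot(inherits(image, "stimulus_image"))
  max_lum <- max(image$luminance, 1e-12)
  q <- round(image$luminance / max_lum * 65535)
  hi <- q %/% 256L
  lo <- q %% 256L
  rgb <- array(0, c(nrow(q), ncol(q), 3))
  rgb[, , 1] <- hi / 255
  rgb[, , 2] <- lo / 255
  png::writePNG(rgb, paste0(prefix, ".png"))
  key <- paste(signif(image$chroma_x, 10), signif(image$chroma_y, 10))
  pal <- !duplicated(key)
  pal_x <- image$chroma_x[pal]
  pal_y <- image$chroma_y[pal]
  idx <- match(key, key[pal]) - 1L
  if (max(idx) > 255L) stop("more than 256 distinct chromaticities",
    call. = FALSE
  )
  png::writePNG(
    matrix(idx / 255, nrow(image$luminance), ncol(image$luminance)),
    paste0(prefix, "_chroma.png")
  )
  side <- list(
    luminance_encoding = "16-bit: high/low byte in PNG channels 1-2",
    max_luminance = max_lum,
    geometry = unclass(image$geometry),
    palette = list(x = as.numeric(pal_x), y = as.numeric(pal_y)),
    provenance = provenance_for_sidecar(image$provenance)
  )
  yaml::write_yaml(side, paste0(prefix, ".yaml"))
  invisible(prefix)
}

# Masks are large index vectors; keep sidecars small by dropping them.
provenance_for_sidecar <- function(prov) {
  prov$fixation_idx <- NULL
  prov$patch_idx <- NULL
  prov
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(prefix) {
  side <- yaml::read_yaml(paste0(prefix, ".yaml"))
  rgb <- png::readPNG(paste0(prefix, ".png"))
  q <- round(rgb[, , 1] * 255) * 256 + round(rgb[, , 2] * 255)
  lum <- q / 65535 * side$max_luminance
  idx <- round(png::readPNG(paste0(prefix, "_chroma.png")) * 255) + 1L
  cx <- matrix(side$palette$x[idx], nrow(lum), ncol(lum))
  cy <- matrix(side$palette$y[idx], nrow(lum), ncol(lum))
  geom <- do.call(display_geometry, side$geometry[c(
    "viewing_distance_cm", "width_deg", "height_deg", "width_px", "height_px"
  )])
  stimulus_image(lum, cx, cy, geom, side$provenance)
}
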