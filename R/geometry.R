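#' Display geometry
#'
#' Viewing geometry of a stimulus display: angular screen size, pixel
#' resolution and viewing distance. Degrees and pixels are related by a
#' linear (small-angle) mapping with pixel centers at half-integer pixel
#' coordinates, so the conversion is exactly invertible.
#'
#' @param viewing_distance_cm Viewing distance in cm.
#' @param width_deg,height_deg Angular screen size in degrees of visual angle.
#' @param width_px,height_px Screen resolution in pixels.
#' @return An object of class `display_geometry`.
#' @export
#' @examples
#' fmri_display()
display_geometry <- function(viewing_distance_cm, width_deg, height_deg,
                             width_px, height_px) {
  vals <- c(viewing_distance_cm, width_deg, height_deg, width_px, height_px)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stop("all display geometry fields must be strictly positive", call. = FALSE)
  }
  structure(
    list(
      viewing_distance_cm = viewing_distance_cm,
      width_deg = width_deg, height_deg = height_deg,
      width_px = as.integer(width_px), height_px = as.integer(height_px)
    ),
    class = "display_geometry"
  )
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf(
    "Display: %.1f x %.1f deg, %d x %d px, %.1f cm viewing distance\n",
    x$width_deg, x$height_deg, x$width_px, x$height_px,
    x$viewing_distance_cm
  ))
  invisible(x)
}

#' @rdname display_geometry
#' @export
fmri_display <- function() {
  display_geometry(69, 31.5, 25.2, 1280, 1024)
}

#' @rdname display_geometry
#' @export
psycho_display <- function() {
  display_geometry(54.4, 31.5, 23.6, 1280, 1024)
}

#' Degrees <-> pixels conversion
#'
#' Linear conversion between degrees of visual angle (origin at screen
#' center, x rightward, y upward) and pixel coordinates (origin at the
#' top-left corner, pixel centers at half-integers).
#'
#' @param geometry A [display_geometry()].
#' @param x_deg,y_deg Angular coordinates in degrees.
#' @param x_px,y_px Pixel coordinates.
#' @return `deg_to_px()` returns a list with `x_px`, `y_px`; `px_to_deg()`
#'   the inverse.
#' @export
deg_to_px <- function(geometry, x_deg, y_deg) {
  sx <- geometry$width_px / geometry$width_deg
  sy <- geometry$height_px / geometry$height_deg
  list(
    x_px = x_deg * sx + geometry$width_px / 2,
    y_px = geometry$height_px / 2 - y_deg * sy
  )
}

#' @rdname deg_to_px
#' @export
px_to_deg <- function(geometry, x_px, y_px) {
  sx <- geometry$width_px / geometry$width_deg
  sy <- geometry$height_px / geometry$height_deg
  list(
    x_deg = (x_px - geometry$width_px / 2) / sx,
    y_deg = (geometry$height_px / 2 - y_px) / sy
  )
}

# Matrices of pixel-center angular coordinates (row = y, col = x).
pixel_grid <- function(geometry) {
  nx <- geometry$width_px
  ny <- geometry$height_px
  cx <- px_to_deg(geometry, seq_len(nx) - 0.5, 0.5)$x_deg
  cy <- px_to_deg(geometry, 0.5, seq_len(ny) - 0.5)$y_deg
  list(
    x = matrix(cx, nrow = ny, ncol = nx, byrow = TRUE),
    y = matrix(cy, nrow = ny, ncol = nx)
  )
}
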