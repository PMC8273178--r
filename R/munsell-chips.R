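# Embedded Munsell chip colorimetry for the patch stimuli.
#
# The stimuli use the ten principal Munsell hues (5R ... 5RP) at Value 5 and
# Chroma 2/4/6, plus the neutral N5 for the achromatic condition. Their CIE
# 1931 chromaticities, derived from the Munsell renotation colour map and
# adapted to the D65/sRGB white point, are embedded as a plain-text table so
# that stimulus generation needs no colorimetry dependency at run time.

the <- new.env(parent = emptyenv())

munsell_hues <- function() {
  c("5R", "5YR", "5Y", "5GY", "5G", "5BG", "5B", "5PB", "5P", "5RP")
}

#' D65 white point chromaticity
#'
#' CIE 1931 chromaticity of standard illuminant D65 as realised by the sRGB
#' primaries; neutral (chroma 0) chips sit exactly on this point.
#'
#' @return Named numeric vector `c(x, y)`.
#' @export
d65_white <- function() c(x = 0.312727, y = 0.329023)

munsell_chip_table <- function() {
  if (is.null(the$chips)) {
    path <- system.file("extdata", "munsell_chips_d65.csv",
      package = "chromsupp", mustWork = TRUE
    )
    the$chips <- utils::read.csv(path, comment.char = "#",
      stringsAsFactors = FALSE
    )
  }
  the$chips
}

#' Luminance factor of a Munsell Value
#'
#' The ASTM D1535 quintic relating Munsell Value V to the luminance factor Y
#' (percent, relative to magnesium oxide; Y(10) = 102.57).
#'
#' @param value Munsell Value (0-10).
#' @return Luminance factor in percent.
#' @export
#' @examples
#' munsell_value_luminance(5) # ~19.77
munsell_value_luminance <- function(value) {
  stopifnot(is.numeric(value), value >= 0, value <= 10)
  1.2219 * value - 0.23111 * value^2 + 0.23951 * value^3 -
    0.021009 * value^4 + 0.0008404 * value^5
}

#' White luminance that maps Value 5 to a target chip luminance
#'
#' The displays are characterised here by the luminance of their reference
#' white (Munsell Value 10). The paradigm's two displays are specified
#' instead by the luminance of the Value-5 chips (16.0 cd/m2 for the scanner
#' projector, 19.8 cd/m2 for the psychophysics CRT); this helper inverts the
#' scaling.
#'
#' @param value5_luminance Target luminance of a Value-5 chip, cd/m2.
#' @return White (Value 10) luminance in cd/m2.
#' @export
white_for_value5 <- function(value5_luminance) {
  value5_luminance * munsell_value_luminance(10) / munsell_value_luminance(5)
}

#' Look up a Munsell chip as CIE xyY
#'
#' Returns the chromaticity and absolute luminance of a Munsell chip from the
#' embedded renotation-derived table. Luminance depends on Value only (via the
#' ASTM D1535 polynomial) and on the display white scaling, never on hue or
#' chroma, so every chip in one stimulus shares the same luminance.
#'
#' @param hue_code One of `"5R" ... "5RP"`, or `"N"` for neutral.
#' @param value Munsell Value; only 5 is covered by the embedded table.
#' @param chroma Munsell Chroma: 0 (neutral), 2, 4 or 6.
#' @param white_luminance Luminance of the display white (Value 10), cd/m2.
#'   The default maps Value 5 to 16.0 cd/m2 (scanner projector); use
#'   `white_for_value5(19.8)` for the psychophysics display.
#' @return An object of class `munsell_chip`: a list with `hue`, `value`,
#'   `chroma`, `x`, `y`, `luminance`.
#' @export
#' @examples
#' munsell_to_xyY("N", 5, 0)           # D65 white point, ~16 cd/m2
#' munsell_to_xyY("5R", 5, 6)$x
munsell_to_xyY <- function(hue_code, value = 5, chroma,
                           white_luminance = white_for_value5(16.0)) {
  if (chroma == 0) hue_code <- "N"
  tab <- munsell_chip_table()
  row <- tab[tab$hue == hue_code & tab$value == value & tab$chroma == chroma, ]
  if (nrow(row) != 1L) {
    stop("unsupported Munsell chip: ", hue_code, " ", value, "/", chroma,
      " (embedded table covers Value 5, Chroma 0/2/4/6, hues ",
      paste(c(munsell_hues(), "N"), collapse = " "), ")",
      call. = FALSE
    )
  }
  lum <- white_luminance * munsell_value_luminance(value) /
    munsell_value_luminance(10)
  structure(
    list(
      hue = hue_code, value = value, chroma = chroma,
      x = row$x, y = row$y, luminance = lum
    ),
    class = "munsell_chip"
  )
}

#' @export
print.munsell_chip <- function(x, ...) {
  cat(sprintf(
    "Munsell chip %s %g/%g: xy = (%.4f, %.4f), %.2f cd/m2\n",
    x$hue, x$value, x$chroma, x$x, x$y, x$luminance
  ))
  invisible(x)
}

#' Chip set for one chroma condition
#'
#' The ten patch colors of one stimulus: in condition `"/0"` ten identical
#' neutral chips, otherwise one chip per principal hue, all at the given
#' chroma and Value 5. All ten luminances are equal by construction.
#'
#' @param chroma_condition `"/0"`, `"/2"`, `"/4"` or `"/6"`.
#' @param white_luminance Display white luminance, as in [munsell_to_xyY()].
#' @return A data frame with ten rows and columns `hue`, `value`, `chroma`,
#'   `x`, `y`, `luminance`.
#' @export
#' @examples
#' chip_set("/6")
chip_set <- function(chroma_condition,
                     white_luminance = white_for_value5(16.0)) {
  check_chroma(chroma_condition)
  chroma <- as.numeric(sub("^/", "", chroma_condition))
  hues <- if (chroma == 0) rep("N", 10L) else munsell_hues()
  chips <- lapply(hues, munsell_to_xyY,
    value = 5, chroma = chroma,
    white_luminance = white_luminance
  )
  do.call(rbind, lapply(chips, function(ch) {
    data.frame(
      hue = ch$hue, value = ch$value, chroma = ch$chroma,
      x = ch$x, y = ch$y, luminance = ch$luminance
    )
  }))
}

#' Excitation purity of a chromaticity relative to D65
#'
#' Distance from the white point as a fraction of the distance from the white
#' point to the spectral locus along the same direction is not needed here;
#' for comparing chips of one hue at different chroma the *relative* colori-
#' metric purity (Euclidean distance from the D65 point in the xy plane)
#' suffices and is monotone in it.
#'
#' @param x,y CIE 1931 chromaticity coordinates.
#' @return Euclidean xy distance from the D65 white point.
#' @export
purity_from_white <- function(x, y) {
  w <- d65_white()
  sqrt((x - w["x"])^2 + (y - w["y"])^2)[[1]]
}
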