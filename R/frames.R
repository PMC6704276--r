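#' Coordinate frame
#'
#' A named 2-D pixel coordinate system. The pipeline chains four frames:
#' `"msi"` (the MSI pixel grid), `"optical"` (high-resolution optical image
#' of the section with matrix), `"he"` (H&E image after staining), and
#' `"lmd"` (the microdissection stage). User-defined names are allowed.
#'
#' Convention in this package: pixel indices are 0-based, `x` is the column,
#' `y` is the row, `y` increases downward, and a coordinate refers to the
#' pixel center.
#'
#' @param name frame name, non-empty string.
#' @param pixel_size optional physical pixel size in micrometers; either a
#'   single value or `c(x, y)`. Must be strictly positive.
#' @return an object of class `"msi2lmd_frame"`.
#' @examples
#' optical <- frame("optical", pixel_size = c(2.076, 2.084))
#' @export
frame <- function(name, pixel_size = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.null(pixel_size)) {
    pixel_size <- as.numeric(pixel_size)
    if (length(pixel_size) == 1) pixel_size <- rep(pixel_size, 2)
    stopifnot(length(pixel_size) == 2, all(is.finite(pixel_size)),
              all(pixel_size > 0))
    names(pixel_size) <- c("x", "y")
  }
  structure(list(name = name, pixel_size = pixel_size),
            class = "msi2lmd_frame")
}

#' @export
print.msi2lmd_frame <- function(x, ...) {
  cat("<frame>", x$name)
  if (!is.null(x$pixel_size))
    cat(sprintf("  (%.4g x %.4g um/px)", x$pixel_size[1], x$pixel_size[2]))
  cat("\n")
  invisible(x)
}

frame_name <- function(f) {
  if (inherits(f, "msi2lmd_frame")) f$name else as.character(f)
}

#' Convert an image resolution in dpi to a pixel size in micrometers
#'
#' One inch is 25400 micrometers, so a scanner resolution of `dpi` dots per
#' inch corresponds to `25400 / dpi` micrometers per pixel. At the 1:4
#' downscaled resolutions used for the optical and H&E scans
#' (12,235 x 12,189 dpi) this gives 2.076 and 2.084 um.
#'
#' @param dpi dots per inch, strictly positive.
#' @return micrometers per pixel.
#' @examples
#' dpi_to_micrometers(12235)  # 2.076
#' @export
dpi_to_micrometers <- function(dpi) {
  stopifnot(is.numeric(dpi), all(is.finite(dpi)))
  if (any(dpi <= 0)) stop("'dpi' must be strictly positive")
  25400 / dpi
}
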