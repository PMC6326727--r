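#' Two-channel aggregate image
#'
#' Container for a calibrated red/green fluorescence raster of a cell
#' aggregate field, as captured in coaggregation assays of differentially
#' labelled cell populations.
#'
#' @param red,green Numeric matrices of identical dimensions holding
#'   non-negative pixel intensities for the red and green channels.
#' @param um_per_px Microns per pixel (isotropic calibration).
#' @param cell_diameter_px Nominal diameter of a single cell, in pixels.
#'
#' @return An object of class `two_channel_image` with elements `red`,
#'   `green`, `um_per_px` and `cell_diameter_px`.
#' @export
two_channel_image <- function(red, green, um_per_px = 0.9,
                              cell_diameter_px = 20) {
  if (!is.matrix(red) || !is.matrix(green))
    stop("'red' and 'green' must be matrices")
  if (!identical(dim(red), dim(green)))
    stop("red and green channels must have identical dimensions")
  if (any(red < 0) || any(green < 0))
    stop("pixel intensities must be non-negative")
  if (!is.numeric(cell_diameter_px) || cell_diameter_px <= 0)
    stop("'cell_diameter_px' must be positive")
  if (!is.numeric(um_per_px) || um_per_px <= 0)
    stop("'um_per_px' must be positive")
  structure(
    list(red = red, green = green, um_per_px = um_per_px,
         cell_diameter_px = cell_diameter_px),
    class = "two_channel_image"
  )
}

#' @export
print.two_channel_image <- function(x, ...) {
  d <- dim(x$red)
  cat(sprintf(
    "Two-channel image: %d x %d px (%.2f um/px, cell diameter %g px)\n",
    d[1], d[2], x$um_per_px, x$cell_diameter_px))
  cat(sprintf("  red:   max %.3g, %.1f%% nonzero\n",
              max(x$red), 100 * mean(x$red > 0)))
  cat(sprintf("  green: max %.3g, %.1f%% nonzero\n",
              max(x$green), 100 * mean(x$green > 0)))
  invisible(x)
}

#' Write / read a two-channel image as a paged TIFF
#'
#' The image is stored as a single TIFF file with two pages, red first then
#' green, intensities rescaled to \[0, 1\] by the supplied `scale`.
#'
#' @param image A [two_channel_image()].
#' @param path Output file path.
#' @param scale Intensity corresponding to 1.0 in the file; defaults to the
#'   image maximum (or 1 for a blank image).
#' @return `write_tcimage` returns `path` invisibly; `read_tcimage` returns a
#'   [two_channel_image()].
#' @export
write_tcimage <- function(image, path, scale = NULL) {
  stopifnot(inherits(image, "two_channel_image"))
  if (is.null(scale)) scale <- max(max(image$red), max(image$green), 1)
  tiff::writeTIFF(list(image$red / scale, image$green / scale), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_tcimage
#' @param um_per_px,cell_diameter_px Calibration to attach on read (TIFF
#'   pages carry no calibration metadata here).
#' @export
read_tcimage <- function(path, um_per_px = 0.9, cell_diameter_px = 20) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2)
    stop("expected a two-page TIFF (red then green), got ", length(pages),
         " page(s)")
  two_channel_image(pages[[1]], pages[[2]], um_per_px = um_per_px,
                    cell_diameter_px = cell_diameter_px)
}
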