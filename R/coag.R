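#' Grid specification for the CoAggregation Index
#'
#' The CoAg grid tiles an aggregate image into non-overlapping squares just
#' slightly larger than a single cell. A square counts as occupied in a
#' channel when at least `occupancy_fraction` of its pixels exceed that
#' channel's intensity threshold; squares occupied in neither channel are
#' "black" and excluded from the index.
#'
#' @param square_side_px Side of the tiling square in pixels. The default,
#'   `NULL`, resolves to `round(1.25 * cell_diameter_px)` of the image at
#'   compute time.
#' @param channel_threshold Per-channel intensity cutoffs as
#'   `c(red, green)`, recycled if length 1. `NULL` (default) uses Otsu's
#'   threshold computed per channel.
#' @param occupancy_fraction Minimum fraction of above-threshold pixels for
#'   a square to count as occupied in a channel. The default 0.02 rejects
#'   single-pixel bleed-through.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(square_side_px = NULL, channel_threshold = NULL,
                      occupancy_fraction = 0.02) {
  if (!is.null(square_side_px) &&
      (!is.numeric(square_side_px) || square_side_px < 1))
    stop("'square_side_px' must be a positive number of pixels")
  if (occupancy_fraction <= 0 || occupancy_fraction > 1)
    stop("'occupancy_fraction' must be in (0, 1]")
  if (!is.null(channel_threshold)) {
    if (!is.numeric(channel_threshold) ||
        !length(channel_threshold) %in% c(1L, 2L))
      stop("'channel_threshold' must be one or two numbers")
    channel_threshold <- rep_len(channel_threshold, 2L)
  }
  structure(list(square_side_px = square_side_px,
                 channel_threshold = channel_threshold,
                 occupancy_fraction = occupancy_fraction),
            class = "grid_spec")
}

# Otsu threshold of one intensity channel; constant channels get a
# threshold above their maximum so they are never "occupied".
otsu_threshold <- function(mat) {
  mx <- max(mat)
  if (mx <= 0 || diff(range(mat)) == 0) return(mx + 1)
  as.numeric(EBImage::otsu(EBImage::Image(mat / mx), range = c(0, 1),
                           levels = 256L)) * mx
}

# Per-square occupancy of one channel over the full tiling.
# Returns a logical vector over squares in column-major square order.
square_occupancy <- function(mat, side, threshold, occupancy_fraction) {
  nr <- nrow(mat) %/% side
  nc <- ncol(mat) %/% side
  mat <- mat[seq_len(nr * side), seq_len(nc * side), drop = FALSE]
  above <- mat > threshold
  # square index of each retained pixel, column-major over the square grid
  ri <- (seq_len(nr * side) - 1L) %/% side
  ci <- (seq_len(nc * side) - 1L) %/% side
  sq <- outer(ri, ci, function(a, b) a + nr * b)
  frac <- as.vector(rowsum(as.numeric(above), group = as.vector(sq))) /
    (side * side)
  frac >= occupancy_fraction
}

#' Compute the CoAggregation Index of a two-channel aggregate image
#'
#' Tiles the image into non-overlapping squares of side
#' `grid$square_side_px` from the top-left origin (partial squares at the
#' right/bottom edges are dropped), discards squares occupied in neither
#' channel, and reports the fraction of the remaining occupied squares that
#' contain both colours. Values below 0.1 indicate segregation of the two
#' populations, 0.1--0.2 interfacing, and above 0.2 increasing intermixing.
#'
#' @param image A [two_channel_image()].
#' @param grid A [grid_spec()]; defaults to the standard grid (square side
#'   1.25 cell diameters, Otsu thresholds, 2% occupancy).
#' @return An object of class `coag_result`: a list with `n_occupied`,
#'   `n_multicolor`, `coag`, `behavior`, and the resolved grid parameters.
#' @examples
#' img <- make_aggregate_image(image_scenario("intermixed", seed = 1))$image
#' compute_coag(img)
#' @export
compute_coag <- function(image, grid = grid_spec()) {
  stopifnot(inherits(image, "two_channel_image"), inherits(grid, "grid_spec"))
  side <- grid$square_side_px
  if (is.null(side)) side <- round(1.25 * image$cell_diameter_px)
  side <- as.integer(side)
  if (side < image$cell_diameter_px)
    stop("square side (", side, " px) must be at least one cell diameter (",
         image$cell_diameter_px, " px)")
  if (nrow(image$red) < side || ncol(image$red) < side)
    stop("image smaller than a single grid square")
  thr <- grid$channel_threshold
  if (is.null(thr))
    thr <- c(otsu_threshold(image$red), otsu_threshold(image$green))
  occ_r <- square_occupancy(image$red, side, thr[1], grid$occupancy_fraction)
  occ_g <- square_occupancy(image$green, side, thr[2], grid$occupancy_fraction)
  n_occ <- sum(occ_r | occ_g)
  if (n_occ == 0L)
    stop("empty field: no occupied squares in either channel")
  n_multi <- sum(occ_r & occ_g)
  coag <- n_multi / n_occ
  structure(list(n_occupied = n_occ, n_multicolor = n_multi, coag = coag,
                 behavior = classify_behavior(coag),
                 square_side_px = side, channel_threshold = thr,
                 occupancy_fraction = grid$occupancy_fraction),
            class = "coag_result")
}

#' @export
print.coag_result <- function(x, ...) {
  cat(sprintf("CoAg = %.4f (%d of %d occupied squares multicolour) -> %s\n",
              x$coag, x$n_multicolor, x$n_occupied, x$behavior))
  invisible(x)
}

#' Classify coaggregation behaviour from a CoAg value
#'
#' CoAg values below 0.1 indicate segregation of the two populations; values
#' in the closed band \[0.1, 0.2\] are typical of populations that interface
#' along a shared boundary; values above 0.2 indicate intermixing.
#'
#' @param coag CoAg value(s) in \[0, 1\]; vectorized.
#' @return Character vector with levels `"segregation"`, `"interface"`,
#'   `"intermix"`.
#' @examples
#' classify_behavior(c(0.07, 0.11, 0.40))
#' @export
classify_behavior <- function(coag) {
  if (!is.numeric(coag) || anyNA(coag) || any(coag < 0) || any(coag > 1))
    stop("'coag' must be numeric in [0, 1]")
  ifelse(coag < 0.1, "segregation",
         ifelse(coag <= 0.2, "interface", "intermix"))
}
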