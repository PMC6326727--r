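#' Scenario for a synthetic two-channel aggregate image
#'
#' Describes a synthetic confocal-like field of red/green cell aggregates at
#' a controlled degree of mixing. Cells are rendered as filled discs with
#' Gaussian intensity falloff; the generator is a pure function of the
#' scenario including its seed.
#'
#' @param mixing_mode One of `"segregated"` (two disjoint compact blobs at
#'   least two cell diameters apart), `"interfaced"` (two half-aggregates
#'   sharing one straight boundary), `"intermixed"` (both colours randomly
#'   interleaved in one blob), `"single_color"` (green only) or
#'   `"full_overlap"` (both channels drawn on identical pixels).
#' @param n_cells_per_color Number of cells per colour (>= 0).
#' @param cell_diameter_px Cell diameter in pixels (>= 3).
#' @param image_size `c(rows, cols)` in pixels.
#' @param intensity Per-channel peak intensity of a cell centre.
#' @param noise_sd Standard deviation of additive Gaussian background noise
#'   (intensity units); negatives clipped at 0.
#' @param um_per_px Microns per pixel.
#' @param seed Integer seed; regeneration with the same scenario is
#'   bit-identical.
#' @return An object of class `image_scenario`.
#' @export
image_scenario <- function(mixing_mode = c("segregated", "interfaced",
                                           "intermixed", "single_color",
                                           "full_overlap"),
                           n_cells_per_color = 50, cell_diameter_px = 20,
                           image_size = c(1024, 1024), intensity = 1,
                           noise_sd = 0.02, um_per_px = 0.9, seed = 1) {
  mixing_mode <- match.arg(mixing_mode)
  if (n_cells_per_color < 0) stop("'n_cells_per_color' must be >= 0")
  if (cell_diameter_px < 3) stop("'cell_diameter_px' must be >= 3")
  if (length(image_size) != 2 || any(image_size < cell_diameter_px))
    stop("'image_size' must be c(rows, cols), each >= cell_diameter_px")
  if (intensity <= 0) stop("'intensity' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(mixing_mode = mixing_mode,
                 n_cells_per_color = as.integer(n_cells_per_color),
                 cell_diameter_px = cell_diameter_px,
                 image_size = as.integer(image_size),
                 intensity = intensity, noise_sd = noise_sd,
                 um_per_px = um_per_px, seed = as.integer(seed)),
            class = "image_scenario")
}

# paint one cell disc (Gaussian falloff, sigma = diameter/4) into a channel
paint_cell <- function(mat, center, diameter, peak) {
  r <- diameter / 2
  sigma <- diameter / 4
  r0 <- max(1L, floor(center[1] - r)); r1 <- min(nrow(mat), ceiling(center[1] + r))
  c0 <- max(1L, floor(center[2] - r)); c1 <- min(ncol(mat), ceiling(center[2] + r))
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, `+`)
  disc <- peak * exp(-d2 / (2 * sigma^2)) * (d2 <= r^2)
  mat[rows, cols] <- pmax(mat[rows, cols], disc)
  mat
}

# blob radius that accommodates n cells at ~50% packing density
blob_radius <- function(n_cells, cell_diameter) {
  (cell_diameter / 2) * sqrt(max(n_cells, 1) / 0.5)
}

# n random positions inside a (half-)disc around `center`
sample_in_disc <- function(n, center, radius, half = c("none", "left", "right")) {
  half <- match.arg(half)
  theta <- switch(half,
    none  = stats::runif(n, 0, 2 * pi),
    left  = stats::runif(n, pi / 2, 3 * pi / 2),
    right = stats::runif(n, -pi / 2, pi / 2))
  rad <- radius * sqrt(stats::runif(n))
  cbind(center[1] + rad * sin(theta), center[2] + rad * cos(theta))
}

#' Generate a synthetic two-channel aggregate image with ground truth
#'
#' Renders a red/green field of cell aggregates according to the scenario's
#' mixing mode, as a stand-in for confocal images of two differentially
#' labelled cell populations in a coaggregation assay.
#'
#' @param scenario An [image_scenario()].
#' @return List with `image` (a [two_channel_image()]) and `truth` (list:
#'   `expected_behavior`, `centers_red`, `centers_green`, `scenario`).
#' @examples
#' out <- make_aggregate_image(image_scenario("segregated", seed = 3))
#' compute_coag(out$image)
#' @export
make_aggregate_image <- function(scenario) {
  stopifnot(inherits(scenario, "image_scenario"))
  s <- scenario
  dims <- s$image_size
  d <- s$cell_diameter_px
  n <- s$n_cells_per_color
  withr::local_seed(s$seed)
  R <- blob_radius(n, d)                      # one-colour blob
  R2 <- blob_radius(2 * n, d)                 # merged two-colour blob
  mid <- dims / 2
  margin <- d / 2 + 1
  check_fit <- function(radius, center) {
    if (center[1] - radius < margin || center[1] + radius > dims[1] - margin ||
        center[2] - radius < margin || center[2] + radius > dims[2] - margin)
      stop("requested cells cannot fit in the image: blob of radius ",
           round(radius), " px exceeds the ", dims[1], "x", dims[2],
           " px field")
  }
  green_pos <- red_pos <- matrix(numeric(0), 0, 2)
  expected <- NA_character_
  if (n > 0) switch(s$mixing_mode,
    segregated = {
      gap <- 2 * d                            # edge-to-edge blob separation
      offset <- R + gap / 2
      cg <- c(mid[1], mid[2] - offset); cr <- c(mid[1], mid[2] + offset)
      check_fit(R, cg); check_fit(R, cr)
      green_pos <- sample_in_disc(n, cg, R)
      red_pos <- sample_in_disc(n, cr, R)
      expected <- "segregation"
    },
    interfaced = {
      check_fit(R2, mid)
      green_pos <- sample_in_disc(n, mid, R2, half = "left")
      red_pos <- sample_in_disc(n, mid, R2, half = "right")
      expected <- "interface"
    },
    intermixed = {
      check_fit(R2, mid)
      green_pos <- sample_in_disc(n, mid, R2)
      red_pos <- sample_in_disc(n, mid, R2)
      expected <- "intermix"
    },
    single_color = {
      check_fit(R, mid)
      green_pos <- sample_in_disc(n, mid, R)
      expected <- "segregation"
    },
    full_overlap = {
      check_fit(R, mid)
      green_pos <- sample_in_disc(n, mid, R)
      red_pos <- green_pos
      expected <- "intermix"
    })
  red <- green <- matrix(0, dims[1], dims[2])
  for (i in seq_len(nrow(green_pos)))
    green <- paint_cell(green, green_pos[i, ], d, s$intensity)
  for (i in seq_len(nrow(red_pos)))
    red <- paint_cell(red, red_pos[i, ], d, s$intensity)
  if (s$noise_sd > 0) {
    red <- pmax(red + matrix(stats::rnorm(prod(dims), 0, s$noise_sd),
                             dims[1], dims[2]), 0)
    green <- pmax(green + matrix(stats::rnorm(prod(dims), 0, s$noise_sd),
                                 dims[1], dims[2]), 0)
  }
  img <- two_channel_image(red, green, um_per_px = s$um_per_px,
                           cell_diameter_px = d)
  list(image = img,
       truth = list(expected_behavior = expected,
                    centers_red = red_pos, centers_green = green_pos,
                    scenario = s))
}

#' Paint a fixture image of blobs with exact pixel areas
#'
#' Draws disjoint 4-connected blobs of exactly the requested pixel areas in
#' the green channel (red stays blank), for testing particle-size
#' measurement. Each blob is a filled rectangle plus a partial top row.
#'
#' @param areas_px Integer vector of exact blob areas; may be empty (blank
#'   image).
#' @param image_size `c(rows, cols)`.
#' @param gap Minimum pixel gap between blob bounding boxes (>= 2 so blobs
#'   stay disconnected under 8-connectivity).
#' @param intensity Foreground intensity.
#' @param um_per_px,cell_diameter_px Calibration to attach.
#' @return List with `image` (a [two_channel_image()]) and `truth` (list
#'   `areas_px` in blob order).
#' @export
make_size_fixture <- function(areas_px, image_size = c(256, 256), gap = 3,
                              intensity = 1, um_per_px = 0.9,
                              cell_diameter_px = 10) {
  areas_px <- as.integer(areas_px)
  if (any(areas_px < 1)) stop("'areas_px' must be positive")
  if (gap < 2) stop("'gap' must be >= 2 to keep blobs disconnected")
  green <- matrix(0, image_size[1], image_size[2])
  r_cursor <- 2L; c_cursor <- 2L; row_height <- 0L
  for (a in areas_px) {
    w <- ceiling(sqrt(a))
    h_full <- a %/% w
    rem <- a %% w
    h <- h_full + (rem > 0L)
    if (c_cursor + w > image_size[2] - 1L) {    # wrap to next shelf
      c_cursor <- 2L
      r_cursor <- r_cursor + row_height + gap
      row_height <- 0L
    }
    if (r_cursor + h > image_size[1] - 1L || c_cursor + w > image_size[2] - 1L)
      stop("blobs of the requested areas do not fit in the image")
    if (h_full > 0L)
      green[r_cursor:(r_cursor + h_full - 1L),
            c_cursor:(c_cursor + w - 1L)] <- intensity
    if (rem > 0L)
      green[r_cursor + h_full, c_cursor:(c_cursor + rem - 1L)] <- intensity
    c_cursor <- c_cursor + w + gap
    row_height <- max(row_height, h)
  }
  img <- two_channel_image(red = matrix(0, image_size[1], image_size[2]),
                           green = green, um_per_px = um_per_px,
                           cell_diameter_px = cell_diameter_px)
  list(image = img, truth = list(areas_px = areas_px))
}
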