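# shared fixtures built in code

# image whose grid squares are painted wholesale: `spec` is a matrix of
# "g" / "r" / "b" (both) / "." over the square grid
painted_field <- function(spec, side = 32, cell_diameter = 20) {
  red <- green <- matrix(0, nrow(spec) * side, ncol(spec) * side)
  for (i in seq_len(nrow(spec))) for (j in seq_len(ncol(spec))) {
    rows <- ((i - 1) * side + 1):(i * side)
    cols <- ((j - 1) * side + 1):(j * side)
    if (spec[i, j] %in% c("g", "b")) green[rows, cols] <- 1
    if (spec[i, j] %in% c("r", "b")) red[rows, cols] <- 1
  }
  two_channel_image(red, green, cell_diameter_px = cell_diameter)
}

# independent CoAg oracle: explicit per-square pixel enumeration with an
# ordinary double loop, fixed thresholds, no shared code with compute_coag
brute_force_coag <- function(image, side, thr, occ_frac = 0.02) {
  nr <- nrow(image$red) %/% side
  nc <- ncol(image$red) %/% side
  n_occ <- 0L; n_multi <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rows <- ((i - 1) * side + 1):(i * side)
    cols <- ((j - 1) * side + 1):(j * side)
    r_on <- mean(image$red[rows, cols] > thr[1]) >= occ_frac
    g_on <- mean(image$green[rows, cols] > thr[2]) >= occ_frac
    if (r_on || g_on) n_occ <- n_occ + 1L
    if (r_on && g_on) n_multi <- n_multi + 1L
  }
  list(n_occupied = n_occ, n_multicolor = n_multi,
       coag = if (n_occ > 0) n_multi / n_occ else NA_real_)
}

# 90 degree clockwise rotation of a matrix
rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
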