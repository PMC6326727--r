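#' 8-connected component labelling of a binary mask
#'
#' Labels connected sets of foreground pixels using 8-connectivity (pixels
#' touching edge- or corner-wise belong to the same component), matching the
#' convention of common particle-analysis workflows.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered 1..k in order of their first pixel (column-major).
#' @export
label_components <- function(mask) {
  mask <- mask != 0
  storage.mode(mask) <- "logical"
  idx <- which(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  nc <- ncol(mask)
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  # neighbour offsets covering each unordered 8-neighbour pair once:
  # south, east, south-east, north-east
  edges <- list()
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- row + off[1]; c2 <- col + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (any(ok))
      edges[[length(edges) + 1L]] <-
        cbind(pos[idx[ok]], pos[cbind(r2[ok], c2[ok])])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  # renumber by first occurrence so labels are deterministic
  comp <- match(comp, unique(comp))
  lab[idx] <- comp
  lab
}

#' Measure aggregate sizes in one channel
#'
#' Binarizes the channel at `threshold`, labels 8-connected components, and
#' removes aggregates smaller than `min_cells` cells (estimated as pixel
#' area / `single_cell_area_px`). The minimum-size filter excludes dividing
#' cells and single cells not participating in aggregation; aggregates of
#' exactly `min_cells` cells are kept.
#'
#' @param channel Numeric intensity matrix (one channel), or a
#'   [two_channel_image()] together with `which`.
#' @param threshold Intensity cutoff; pixels strictly above it are
#'   foreground. `NULL` uses Otsu's threshold.
#' @param single_cell_area_px Pixel area of one cell.
#' @param min_cells Minimum aggregate size in cells; default 3.
#' @param um_per_px Microns per pixel, for areas in square microns.
#' @param which For a `two_channel_image`, which channel to measure.
#' @return An object of class `aggregate_sizes`: list with `aggregates`
#'   (data frame: `id`, `area_px`, `n_cells`, `area_um2`), `n_discarded`,
#'   `discarded_area_px`, `mean_area_px`, `mean_area_um2`, and the filter
#'   settings. A blank channel gives zero aggregates, not an error.
#' @export
measure_aggregates <- function(channel, threshold = NULL,
                               single_cell_area_px, min_cells = 3,
                               um_per_px = 0.9,
                               which = c("green", "red")) {
  if (inherits(channel, "two_channel_image")) {
    which <- match.arg(which)
    um_per_px <- channel$um_per_px
    channel <- channel[[which]]
  }
  stopifnot(is.matrix(channel), single_cell_area_px > 0, min_cells >= 0)
  if (is.null(threshold)) threshold <- otsu_threshold(channel)
  if (threshold < 0) stop("'threshold' must be non-negative")
  mask <- channel > threshold
  lab <- label_components(mask)
  areas <- if (max(lab) > 0) tabulate(lab[lab > 0L]) else integer(0)
  min_area <- min_cells * single_cell_area_px
  keep <- areas >= min_area
  agg <- data.frame(
    id = seq_along(areas)[keep],
    area_px = areas[keep],
    n_cells = areas[keep] / single_cell_area_px,
    area_um2 = areas[keep] * um_per_px^2
  )
  structure(list(
    aggregates = agg,
    n_discarded = sum(!keep),
    discarded_area_px = sum(areas[!keep]),
    mean_area_px = if (nrow(agg)) mean(agg$area_px) else NA_real_,
    mean_area_um2 = if (nrow(agg)) mean(agg$area_um2) else NA_real_,
    threshold = threshold, single_cell_area_px = single_cell_area_px,
    min_cells = min_cells, um_per_px = um_per_px,
    labels = lab
  ), class = "aggregate_sizes")
}

#' @export
print.aggregate_sizes <- function(x, ...) {
  cat(sprintf(
    "%d aggregate(s) >= %g cells (%d smaller component(s) discarded)\n",
    nrow(x$aggregates), x$min_cells, x$n_discarded))
  if (nrow(x$aggregates))
    cat(sprintf("  mean area: %.1f px (%.1f um^2)\n",
                x$mean_area_px, x$mean_area_um2))
  invisible(x)
}

#' Mean aggregate size across a rotation-speed series
#'
#' Summarizes aggregate-size measurements grouped by rotation speed (RPM),
#' as in shear-titration assays where aggregates are imaged after stepwise
#' increases in rotational speed. Images within a replicate are averaged
#' first; replicate means are then averaged per RPM.
#'
#' @param results List of [measure_aggregates()] results (or data frames
#'   with an `area_um2` column).
#' @param rpm Numeric/character vector of RPM labels, one per result.
#' @param replicate Replicate labels, one per result; defaults to one
#'   replicate per image.
#' @param known_rpm RPM levels considered standard for the assay; other
#'   labels trigger a warning but are retained.
#' @return Data frame with one row per RPM: `rpm`, `n_replicates`,
#'   `mean_size_um2`, `sem_size_um2`, sorted by RPM.
#' @export
speed_series <- function(results, rpm, replicate = seq_along(results),
                         known_rpm = c(15, 120, 160, 200, 220)) {
  if (length(results) == 0L) stop("no results supplied")
  if (length(rpm) != length(results) || length(replicate) != length(results))
    stop("'rpm' and 'replicate' must have one entry per result")
  unknown <- setdiff(unique(rpm), known_rpm)
  if (length(unknown))
    warning("unrecognized RPM label(s): ", paste(unknown, collapse = ", "),
            " (retained as given)")
  size <- vapply(results, function(r) {
    if (inherits(r, "aggregate_sizes")) r$mean_area_um2
    else mean(r$area_um2)
  }, numeric(1))
  out <- do.call(rbind, lapply(split(seq_along(size), rpm), function(i) {
    s <- summarize_replicates(size[i], replicate[i])
    data.frame(rpm = rpm[i[1]], n_replicates = s$n_replicates,
               mean_size_um2 = s$mean, sem_size_um2 = s$sem)
  }))
  out <- out[order(as.numeric(as.character(out$rpm))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize values over replicates as mean +/- SEM
#'
#' Observations (e.g. per-image CoAg values) are first averaged within each
#' replicate; the reported mean and SEM are then taken over the replicate
#' means, so replicates - not images - are the unit of error.
#'
#' @param values Numeric vector of observations.
#' @param replicate Replicate label per observation.
#' @param condition Optional single condition label carried through.
#' @return Object of class `replicate_summary`: list with `condition`,
#'   `n_replicates`, `replicate_means`, `mean`, `sem` (`NA` with
#'   `sem_defined = FALSE` when only one replicate is present).
#' @examples
#' summarize_replicates(c(0.2, 0.3, 0.4), replicate = 1:3)
#' @export
summarize_replicates <- function(values, replicate, condition = NA_character_) {
  stopifnot(is.numeric(values), length(values) >= 1,
            length(replicate) == length(values))
  if (anyNA(values)) stop("missing values are not allowed")
  rmeans <- tapply(values, replicate, mean)
  n <- length(rmeans)
  structure(list(
    condition = condition,
    n_replicates = n,
    replicate_means = as.numeric(rmeans),
    mean = mean(rmeans),
    sem = if (n > 1) stats::sd(rmeans) / sqrt(n) else NA_real_,
    sem_defined = n > 1
  ), class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  lbl <- if (is.na(x$condition)) "" else paste0(x$condition, ": ")
  if (x$sem_defined)
    cat(sprintf("%smean %.4f +/- %.4f SEM (n = %d replicates)\n",
                lbl, x$mean, x$sem, x$n_replicates))
  else
    cat(sprintf("%smean %.4f (single replicate; SEM undefined)\n",
                lbl, x$mean))
  invisible(x)
}
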