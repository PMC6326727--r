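#' Scenario for a synthetic targeted single-cell count matrix
#'
#' Describes an nCounter-like genes-by-cells panel with designated negative
#' control genes, a low-count null component and a well-separated expressed
#' component on the log2 scale, and known per-cell on/off truth. Control
#' genes are always generated from the null component.
#'
#' The defaults emulate the study conditions of a targeted olfactory-neuron
#' panel: 50 cells, an 8-gene protocadherin target panel whose per-cell
#' expressed counts are uniform on 0..7 (mean 3.5), three negative control
#' genes, and filler genes bringing the panel to 27.
#'
#' @param n_cells Number of cells.
#' @param gene_names All panel genes.
#' @param control_genes Subset of `gene_names` treated as negative
#'   controls (never expressed).
#' @param target_panel Subset over which `per_cell_n_expressed` applies;
#'   default all non-control genes.
#' @param per_cell_n_expressed Integer vector (length `n_cells`) of how
#'   many target-panel genes each cell expresses, or `NULL` to draw
#'   uniformly from `0..length(target_panel) - 1`.
#' @param null_shape,null_scale Gamma parameters of the null component on
#'   the `log2(count + 1)` scale.
#' @param expressed_mean,expressed_sd Normal parameters of the expressed
#'   component on the same scale. `expressed_mean` must exceed the null
#'   mean (`null_shape * null_scale`); the defaults separate the two
#'   components by 7 log2 units mean-to-mean, with the null 99.9th
#'   percentile (counts of ~20) well below the expressed 0.1th percentile
#'   (counts of ~30), i.e. genuinely well-separated components.
#' @param seed Integer seed; same scenario, same matrix, bit for bit.
#' @return Object of class `count_scenario`.
#' @export
count_scenario <- function(n_cells = 50,
                           gene_names = c(
                             paste0("Pcdh", c("1", "7", "9", "11x", "8",
                                              "10", "17", "19")),
                             "Notch2", "Gfap", "Cdh13",
                             paste0("Aux", 1:16)),
                           control_genes = c("Notch2", "Gfap", "Cdh13"),
                           target_panel = NULL,
                           per_cell_n_expressed = NULL,
                           null_shape = 2, null_scale = 0.5,
                           expressed_mean = 8, expressed_sd = 1,
                           seed = 1) {
  if (anyDuplicated(gene_names)) stop("duplicate gene names")
  if (!all(control_genes %in% gene_names))
    stop("control genes must be a subset of gene_names")
  if (is.null(target_panel))
    target_panel <- setdiff(gene_names, control_genes)[
      seq_len(min(8, length(setdiff(gene_names, control_genes))))]
  if (!all(target_panel %in% setdiff(gene_names, control_genes)))
    stop("target panel must be non-control genes")
  if (null_shape <= 0 || null_scale <= 0 || expressed_sd <= 0)
    stop("distribution parameters must be positive")
  if (expressed_mean <= null_shape * null_scale)
    stop("expressed mean (", expressed_mean,
         ") must exceed the null mean (", null_shape * null_scale,
         "): scenario otherwise unidentifiable")
  if (!is.null(per_cell_n_expressed)) {
    per_cell_n_expressed <- as.integer(per_cell_n_expressed)
    if (length(per_cell_n_expressed) != n_cells)
      stop("'per_cell_n_expressed' must have one entry per cell")
    if (any(per_cell_n_expressed < 0) ||
        any(per_cell_n_expressed > length(target_panel)))
      stop("'per_cell_n_expressed' must lie in 0..", length(target_panel))
  }
  structure(list(n_cells = as.integer(n_cells), gene_names = gene_names,
                 control_genes = control_genes, target_panel = target_panel,
                 per_cell_n_expressed = per_cell_n_expressed,
                 null_shape = null_shape, null_scale = null_scale,
                 expressed_mean = expressed_mean, expressed_sd = expressed_sd,
                 seed = as.integer(seed)),
            class = "count_scenario")
}

#' Generate a synthetic count matrix with known on/off truth
#'
#' Draws each gene-in-cell value on the `log2(count + 1)` scale — null
#' entries from the gamma component, expressed entries from the normal
#' component — and back-transforms to non-negative integer counts via
#' `round(2^x - 1)` clipped at 0. The mixture fully specifies the noise (no
#' additional count jitter), so the generator is matched to the caller's
#' model and recovery tests are interpretable.
#'
#' @param scenario A [count_scenario()].
#' @return List with `matrix` (a [count_matrix()]) and `truth` (list:
#'   `expressed` logical genes-x-cells mask, `per_cell_n_expressed`,
#'   `scenario`).
#' @examples
#' out <- make_count_matrix(count_scenario(n_cells = 10, seed = 2))
#' out$matrix
#' @export
make_count_matrix <- function(scenario) {
  stopifnot(inherits(scenario, "count_scenario"))
  s <- scenario
  withr::local_seed(s$seed)
  n_genes <- length(s$gene_names)
  n_exp <- s$per_cell_n_expressed
  if (is.null(n_exp))
    n_exp <- sample(0:(length(s$target_panel) - 1L), s$n_cells,
                    replace = TRUE)
  truth <- matrix(FALSE, n_genes, s$n_cells,
                  dimnames = list(s$gene_names,
                                  sprintf("cell%02d", seq_len(s$n_cells))))
  panel_idx <- match(s$target_panel, s$gene_names)
  for (j in seq_len(s$n_cells))
    if (n_exp[j] > 0)
      truth[sample(panel_idx, n_exp[j]), j] <- TRUE
  x <- matrix(stats::rgamma(n_genes * s$n_cells, shape = s$null_shape,
                            scale = s$null_scale),
              n_genes, s$n_cells)
  n_on <- sum(truth)
  if (n_on > 0)
    x[truth] <- stats::rnorm(n_on, s$expressed_mean, s$expressed_sd)
  counts <- pmax(round(2^x - 1), 0)
  dimnames(counts) <- dimnames(truth)
  list(matrix = count_matrix(counts, control_genes = s$control_genes),
       truth = list(expressed = truth, per_cell_n_expressed = n_exp,
                    scenario = s))
}

#' Generate a synthetic single-cell qPCR Ct table with known truth
#'
#' "On" entries get Ct values around `ct_on_mean`; "off" entries get either
#' a Ct above the off floor or a missing value (no amplification).
#'
#' @param n_cells Number of cells; ignored if `truth` is supplied.
#' @param genes Gene names (rows).
#' @param truth Logical genes-x-cells on/off matrix, or `NULL` to draw each
#'   entry on with probability `p_on`.
#' @param p_on Probability an entry is on when `truth` is `NULL`.
#' @param ct_on_mean Mean Ct of on entries (must be < 30).
#' @param ct_on_sd SD of on Ct values (truncated below 30).
#' @param ct_off_floor Minimum Ct of detected off entries (must be > 30).
#' @param p_missing Probability an off entry is missing rather than
#'   high-Ct.
#' @param seed Integer seed.
#' @return List with `ct` (numeric genes-x-cells matrix, `NA` = not
#'   detected) and `truth` (logical matrix).
#' @export
make_qpcr_table <- function(n_cells = 20,
                            genes = paste0("Pcdh", c("1", "7", "9", "11x",
                                                     "8", "10", "17", "19")),
                            truth = NULL, p_on = 0.3,
                            ct_on_mean = 24, ct_on_sd = 2,
                            ct_off_floor = 33, p_missing = 0.5, seed = 1) {
  if (!(ct_on_mean < 30 && 30 < ct_off_floor))
    stop("require ct_on_mean < 30 < ct_off_floor")
  withr::local_seed(seed)
  if (is.null(truth)) {
    truth <- matrix(stats::runif(length(genes) * n_cells) < p_on,
                    length(genes), n_cells)
  } else {
    truth <- as.matrix(truth) != 0
    n_cells <- ncol(truth)
    if (nrow(truth) != length(genes))
      stop("'truth' must have one row per gene")
  }
  dimnames(truth) <- list(genes, sprintf("cell%02d", seq_len(n_cells)))
  ct <- matrix(NA_real_, length(genes), n_cells, dimnames = dimnames(truth))
  n_on <- sum(truth)
  if (n_on > 0) {
    v <- stats::rnorm(n_on, ct_on_mean, ct_on_sd)
    v[v > 30] <- 30 - stats::runif(sum(v > 30), 0, 30 - ct_on_mean)
    v <- pmax(v, 10)
    ct[truth] <- v
  }
  n_off <- sum(!truth)
  if (n_off > 0) {
    detected <- stats::runif(n_off) >= p_missing
    v <- rep(NA_real_, n_off)
    v[detected] <- ct_off_floor + stats::runif(sum(detected), 0, 40 - ct_off_floor)
    ct[!truth] <- v
  }
  list(ct = ct, truth = truth)
}
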