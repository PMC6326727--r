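#' Gene table for the adhesion simulator
#'
#' Hypothetical adhesion genes with relative apparent adhesive affinities
#' (1 = baseline). Same-gene bonds persist longer the higher the gene's
#' affinity; mismatched-gene bonds are unstable and last a single step.
#'
#' @param name Character vector of unique gene names.
#' @param affinity Positive numeric affinities, recycled to `name`.
#' @return Data frame of class `gene_table` with columns `name`,
#'   `affinity`.
#' @export
gene_table <- function(name = c("A", "B"), affinity = 1) {
  if (anyDuplicated(name)) stop("gene names must be unique")
  affinity <- rep_len(affinity, length(name))
  if (any(affinity <= 0)) stop("affinities must be positive")
  structure(data.frame(name = name, affinity = affinity,
                       stringsAsFactors = FALSE),
            class = c("gene_table", "data.frame"))
}

#' Cell population for the adhesion simulator
#'
#' @param color `"green"` or `"red"` — the population label used by the
#'   coaggregation readout; colour never affects binding itself.
#' @param n_cells Number of cells (default 25, the standard assay size).
#' @param expression Named integer vector: molecule tokens per cell for
#'   each expressed gene (names must appear in the simulation's gene
#'   table). At least one gene must have a positive level.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(color = c("green", "red"), n_cells = 25,
                            expression = c(A = 20)) {
  color <- match.arg(color)
  if (n_cells <= 0) stop("'n_cells' must be positive")
  if (is.null(names(expression)) || any(!nzchar(names(expression))))
    stop("'expression' must be a named vector of token counts")
  if (any(expression < 0) || all(expression == 0))
    stop("expression levels must be >= 0 with at least one positive gene")
  structure(list(color = color, n_cells = as.integer(n_cells),
                 expression = expression),
            class = "population_spec")
}

#' Simulation configuration
#'
#' @param n_steps Time steps per run (default 100).
#' @param date_success Fraction of proposed cell pairings that proceed to a
#'   binding attempt (default 0.75; letting only the majority bind avoids
#'   oscillatory network behaviour).
#' @param burn_in_fraction Initial fraction of steps excluded from the
#'   overall coaggregation average while the network stabilizes (default
#'   0.25).
#' @param base_duration Lifetime in steps of a same-gene bond of the
#'   baseline gene (default 3).
#' @param hetero_duration Lifetime of a mismatched-gene bond (default 1).
#' @param n_repeats Independent repeats per scenario (default 5).
#' @param seed Master seed; per-repeat streams are derived from it
#'   deterministically.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_steps = 100, date_success = 0.75,
                       burn_in_fraction = 0.25, base_duration = 3,
                       hetero_duration = 1, n_repeats = 5, seed = 1) {
  if (date_success < 0 || date_success > 1)
    stop("'date_success' must be in [0, 1]")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("'burn_in_fraction' must be in [0, 1)")
  if (base_duration < 1 || hetero_duration < 1)
    stop("bond durations must be >= 1 step")
  if (n_steps < 1 || n_repeats < 1)
    stop("'n_steps' and 'n_repeats' must be >= 1")
  structure(list(n_steps = as.integer(n_steps), date_success = date_success,
                 burn_in_fraction = burn_in_fraction,
                 base_duration = base_duration,
                 hetero_duration = hetero_duration,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "sim_config")
}

# lifetime of a bond between gene g and gene h, in steps
bond_lifetime <- function(g, h, genes, config, baseline_affinity) {
  if (g != h) return(config$hetero_duration)
  aff <- genes$affinity[match(g, genes$name)]
  max(1L, round(config$base_duration * aff / baseline_affinity))
}

#' Force-directed layout of the current cell-bond network
#'
#' Projects the cell-cell bond graph onto two dimensions with a
#' Fruchterman-Reingold layout; cells bound into the same aggregate land
#' close together, so dating probability can decrease with network
#' distance. Deterministic given the RNG state.
#'
#' @param n_cells Number of cells (nodes).
#' @param bonds Bond data frame (columns `i`, `j`), possibly empty.
#' @return `n_cells` x 2 matrix of coordinates.
#' @export
layout_positions <- function(n_cells, bonds = NULL) {
  g <- igraph::make_empty_graph(n = n_cells, directed = FALSE)
  if (!is.null(bonds) && nrow(bonds)) {
    pairs <- unique(cbind(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j)))
    g <- igraph::add_edges(g, t(pairs))
  }
  igraph::layout_with_fr(g, dim = 2)
}

#' Propose a round of speed-dating pairs
#'
#' Draws a random matching over cells in which closer pairs (in the current
#' layout) are more likely to be paired — sampling weight
#' `1 / (1 + distance)`, pairs drawn sequentially without replacement —
#' and retains each matched pair for a binding attempt with probability
#' `date_success`.
#'
#' @param positions Cells x 2 coordinate matrix.
#' @param date_success Probability a matched pair proceeds.
#' @return Integer matrix with columns `i`, `j` (possibly 0 rows).
#' @export
propose_dates <- function(positions, date_success) {
  n <- nrow(positions)
  if (n < 2 || date_success <= 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  pr <- cbind(i = rep(seq_len(n - 1), times = (n - 1):1),
              j = sequence((n - 1):1, from = 2:n))
  d <- sqrt((positions[pr[, 1], 1] - positions[pr[, 2], 1])^2 +
              (positions[pr[, 1], 2] - positions[pr[, 2], 2])^2)
  w <- 1 / (1 + d)
  matched <- matrix(integer(0), 0, 2)
  alive <- rep(TRUE, nrow(pr))
  while (any(alive)) {
    k <- which(alive)
    pick <- k[sample.int(length(k), 1, prob = w[k])]
    matched <- rbind(matched, pr[pick, ])
    alive <- alive & pr[, 1] != pr[pick, 1] & pr[, 2] != pr[pick, 1] &
      pr[, 1] != pr[pick, 2] & pr[, 2] != pr[pick, 2]
  }
  keep <- stats::runif(nrow(matched)) < date_success
  matched <- matched[keep, , drop = FALSE]
  dimnames(matched) <- list(NULL, c("i", "j"))
  matched
}

# sample one free molecule token from a cell: returns the gene name or NA
draw_free_gene <- function(free_row) {
  tot <- sum(free_row)
  if (tot == 0) return(NA_character_)
  names(free_row)[sample.int(length(free_row), 1, prob = free_row)]
}

#' Attempt to bind two cells through one molecule each
#'
#' Each cell offers one unbound molecule token, drawn with probability
#' proportional to its per-gene free-token counts; if either cell has no
#' free token, no bond forms. The bond's lifetime depends on the gene pair:
#' mismatched genes persist `hetero_duration` step(s); same-gene bonds
#' persist `base_duration` times the gene's affinity ratio to the baseline.
#'
#' @param i,j Cell indices.
#' @param free Cells x genes matrix of free token counts (modified copy
#'   returned).
#' @param genes A [gene_table()].
#' @param config A [sim_config()].
#' @param baseline_affinity Affinity of the scenario's baseline gene.
#' @return List with `bond` (one-row data frame `i`, `j`, `gene_i`,
#'   `gene_j`, `life`, or `NULL`) and the updated `free` matrix.
#' @export
attempt_bind <- function(i, j, free, genes, config, baseline_affinity) {
  gi <- draw_free_gene(free[i, ])
  if (is.na(gi)) return(list(bond = NULL, free = free))
  gj <- draw_free_gene(free[j, ])
  if (is.na(gj)) return(list(bond = NULL, free = free))
  free[i, gi] <- free[i, gi] - 1L
  free[j, gj] <- free[j, gj] - 1L
  life <- bond_lifetime(gi, gj, genes, config, baseline_affinity)
  list(bond = data.frame(i = i, j = j, gene_i = gi, gene_j = gj,
                         life = life, stringsAsFactors = FALSE),
       free = free)
}

#' Instantaneous network coaggregation
#'
#' For each cell with at least one bonded partner, the proportion of
#' distinct partner cells of the other colour; averaged over such cells.
#' Cells with no partners are excluded; if no cell has a partner the value
#' is undefined (`NA`).
#'
#' @param bonds Bond data frame (columns `i`, `j`).
#' @param colors Character vector of cell colours.
#' @return Number in \[0, 1\], or `NA` when no cell is bonded.
#' @export
instantaneous_coag <- function(bonds, colors) {
  if (is.null(bonds) || nrow(bonds) == 0) return(NA_real_)
  pairs <- unique(cbind(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j)))
  edges <- rbind(pairs, pairs[, 2:1, drop = FALSE])   # both directions
  diff_col <- colors[edges[, 1]] != colors[edges[, 2]]
  frac <- tapply(diff_col, edges[, 1], mean)
  mean(frac)
}

#' Run the Monte Carlo cell-binding simulation
#'
#' Simulates two coloured cell populations binding through their expressed
#' adhesion genes as a dynamic cell-cell network. Each step: bond lifetimes
#' are decremented and expired bonds release their tokens; the network is
#' re-projected with a force-directed layout; cells "speed date" (closer
#' cells pair up more often, a fraction `date_success` of pairs proceed);
#' proceeding pairs attempt a molecule-level bond; and the instantaneous
#' network coaggregation is recorded. The overall in-silico coaggregation
#' of a run is the mean of the instantaneous values after burn-in; the
#' scenario is repeated `n_repeats` times with derived seeds.
#'
#' @param populations List of two [population_spec()]s (one green, one
#'   red).
#' @param genes A [gene_table()] covering all expressed genes.
#' @param config A [sim_config()].
#' @param baseline_gene Gene whose affinity anchors same-gene bond
#'   lifetimes; default the lowest-affinity gene in `genes`.
#' @return Object of class `sim_result`: list with `overall` (mean of
#'   per-repeat values), `per_repeat`, `per_step` (steps x repeats matrix
#'   of instantaneous values), `n_undefined_steps`, `config`, `genes`,
#'   `populations`.
#' @examples
#' pops <- list(population_spec("green", 10, c(A = 10)),
#'              population_spec("red", 10, c(A = 10)))
#' run_simulation(pops, gene_table("A", 1),
#'                sim_config(n_steps = 20, n_repeats = 2, seed = 1))
#' @export
run_simulation <- function(populations, genes, config = sim_config(),
                           baseline_gene = NULL) {
  stopifnot(inherits(genes, "gene_table"), inherits(config, "sim_config"))
  if (length(populations) != 2 ||
      !all(vapply(populations, inherits, logical(1), "population_spec")))
    stop("'populations' must be a list of two population_spec objects")
  expr_genes <- unique(unlist(lapply(populations,
                                     function(p) names(p$expression))))
  if (!all(expr_genes %in% genes$name))
    stop("expressed genes missing from the gene table: ",
         paste(setdiff(expr_genes, genes$name), collapse = ", "))
  if (is.null(baseline_gene))
    baseline_gene <- genes$name[which.min(genes$affinity)]
  baseline_affinity <- genes$affinity[match(baseline_gene, genes$name)]
  if (is.na(baseline_affinity)) stop("unknown baseline gene")

  colors <- unlist(lapply(populations,
                          function(p) rep(p$color, p$n_cells)))
  n_cells <- length(colors)
  levels <- matrix(0L, n_cells, nrow(genes),
                   dimnames = list(NULL, genes$name))
  at <- 0L
  for (p in populations) {
    idx <- at + seq_len(p$n_cells)
    levels[idx, names(p$expression)] <-
      matrix(as.integer(p$expression), p$n_cells, length(p$expression),
             byrow = TRUE)
    at <- at + p$n_cells
  }

  withr::local_seed(config$seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, config$n_repeats)
  burn_in <- floor(config$burn_in_fraction * config$n_steps)

  one_repeat <- function(rs) {
    withr::local_seed(rs)
    free <- levels
    bonds <- data.frame(i = integer(0), j = integer(0),
                        gene_i = character(0), gene_j = character(0),
                        life = integer(0), stringsAsFactors = FALSE)
    trace <- rep(NA_real_, config$n_steps)
    for (step in seq_len(config$n_steps)) {
      if (nrow(bonds)) {                       # expire and release tokens
        bonds$life <- bonds$life - 1L
        gone <- bonds$life <= 0L
        if (any(gone)) {
          for (k in which(gone)) {
            free[bonds$i[k], bonds$gene_i[k]] <-
              free[bonds$i[k], bonds$gene_i[k]] + 1L
            free[bonds$j[k], bonds$gene_j[k]] <-
              free[bonds$j[k], bonds$gene_j[k]] + 1L
          }
          bonds <- bonds[!gone, , drop = FALSE]
        }
      }
      pos <- layout_positions(n_cells, bonds)
      dates <- propose_dates(pos, config$date_success)
      for (k in seq_len(nrow(dates))) {
        res <- attempt_bind(dates[k, 1], dates[k, 2], free, genes, config,
                            baseline_affinity)
        if (!is.null(res$bond)) {
          free <- res$free
          bonds <- rbind(bonds, res$bond)
        }
      }
      # token conservation: bound + free tokens equal configured levels
      used <- table(factor(c(bonds$gene_i, bonds$gene_j),
                           levels = colnames(levels)))
      stopifnot(colSums(free) + as.integer(used) == colSums(levels))
      trace[step] <- instantaneous_coag(bonds, colors)
    }
    trace
  }

  per_step <- vapply(repeat_seeds, one_repeat, numeric(config$n_steps))
  post <- per_step[(burn_in + 1):config$n_steps, , drop = FALSE]
  per_repeat <- colMeans(post, na.rm = TRUE)
  per_repeat[is.nan(per_repeat)] <- NA_real_
  structure(list(
    overall = mean(per_repeat, na.rm = TRUE),
    per_repeat = per_repeat,
    per_step = per_step,
    n_undefined_steps = sum(is.na(post)),
    burn_in_steps = burn_in,
    config = config, genes = genes, populations = populations,
    baseline_gene = baseline_gene
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "In-silico coaggregation: %.4f (mean of %d repeat(s): %s)\n",
    x$overall, length(x$per_repeat),
    paste(sprintf("%.3f", x$per_repeat), collapse = ", ")))
  if (x$n_undefined_steps > 0)
    cat(sprintf("  %d post-burn-in step(s) had no bonded cells (excluded)\n",
                x$n_undefined_steps))
  invisible(x)
}

#' @export
plot.sim_result <- function(x, ...) {
  graphics::matplot(x$per_step, type = "l", lty = 1,
          col = grDevices::grey.colors(ncol(x$per_step), 0.2, 0.7),
          xlab = "time step", ylab = "instantaneous coaggregation", ...)
  graphics::abline(v = x$burn_in_steps + 0.5, lty = 2)
  graphics::abline(h = x$overall, col = "red3")
  invisible(x)
}

# token split of a 20-token pool between two genes at ratio r:1,
# any nonzero gene keeps at least one token
split_tokens <- function(ratio, pool = 20L) {
  a <- round(pool * ratio / (ratio + 1))
  a <- min(max(a, 1L), pool - 1L)
  c(a = as.integer(a), b = as.integer(pool - a))
}

#' Scenario presets for the mismatch-simulation sweep
#'
#' Builds the two populations of a mismatch coaggregation scenario with a
#' 20-token expression budget per cell:
#' \describe{
#'   \item{`single_vs_double`}{green expresses the baseline gene B only;
#'     red co-expresses B plus the higher-affinity gene A (split
#'     `expr_ratio`:1 A:B). The in-silico analogue of mixing cells carrying
#'     one protocadherin with cells carrying that one plus a stronger
#'     second.}
#'   \item{`single_vs_double_strong`}{green expresses A only; red
#'     co-expresses A and B — the single population carries the stronger
#'     gene.}
#'   \item{`full_mismatch`}{green expresses A only, red B only; no shared
#'     gene.}
#' }
#'
#' @param preset Preset name.
#' @param affinity_ratio Affinity of A relative to B (B fixed at 1).
#' @param expr_ratio A:B token ratio in the co-expressing population.
#' @param n_cells Cells per population.
#' @return List with `populations`, `genes`, `baseline_gene`.
#' @export
sim_preset <- function(preset = c("single_vs_double",
                                  "single_vs_double_strong",
                                  "full_mismatch"),
                       affinity_ratio = 1, expr_ratio = 1, n_cells = 25) {
  preset <- match.arg(preset)
  if (affinity_ratio <= 0 || expr_ratio <= 0)
    stop("ratios must be positive")
  genes <- gene_table(c("A", "B"), c(affinity_ratio, 1))
  tk <- split_tokens(expr_ratio)
  pops <- switch(preset,
    single_vs_double = list(
      population_spec("green", n_cells, c(B = 20)),
      population_spec("red", n_cells, c(A = tk[["a"]], B = tk[["b"]]))),
    single_vs_double_strong = list(
      population_spec("green", n_cells, c(A = 20)),
      population_spec("red", n_cells, c(A = tk[["a"]], B = tk[["b"]]))),
    full_mismatch = list(
      population_spec("green", n_cells, c(A = 20)),
      population_spec("red", n_cells, c(B = 20))))
  list(populations = pops, genes = genes, baseline_gene = "B")
}

#' Sweep in-silico coaggregation over affinity and expression ratios
#'
#' Runs one simulation scenario per grid point of affinity ratio x
#' expression ratio and reports the overall in-silico coaggregation with
#' its Monte Carlo spread over repeats.
#'
#' @param affinity_ratios Numeric grid, default `1:10`.
#' @param expr_ratios Numeric grid of A:B expression ratios in the
#'   co-expressing population, default `c(1, 2, 5, 10, 20)`.
#' @param preset Passed to [sim_preset()].
#' @param config A [sim_config()]; each grid point derives its own seeds
#'   from `config$seed` and the grid coordinates.
#' @param n_cells Cells per population.
#' @return Data frame of class `coag_sweep`: `affinity_ratio`,
#'   `expr_ratio`, `overall`, `mc_sd`, plus per-repeat columns.
#' @export
sweep_simulation <- function(affinity_ratios = 1:10,
                             expr_ratios = c(1, 2, 5, 10, 20),
                             preset = "single_vs_double",
                             config = sim_config(), n_cells = 25) {
  if (!length(affinity_ratios) || !length(expr_ratios))
    stop("ratio grids must be non-empty")
  grid <- expand.grid(affinity_ratio = affinity_ratios,
                      expr_ratio = expr_ratios)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    sc <- sim_preset(preset, grid$affinity_ratio[g], grid$expr_ratio[g],
                     n_cells)
    cfg <- config
    cfg$seed <- (config$seed + 7919L * g) %% .Machine$integer.max
    res <- run_simulation(sc$populations, sc$genes, cfg,
                          baseline_gene = sc$baseline_gene)
    c(overall = res$overall,
      mc_sd = stats::sd(res$per_repeat),
      stats::setNames(res$per_repeat,
                      paste0("repeat", seq_along(res$per_repeat))))
  })
  out <- cbind(grid, do.call(rbind, rows))
  class(out) <- c("coag_sweep", "data.frame")
  out
}

#' @export
plot.coag_sweep <- function(x, ...) {
  er <- sort(unique(x$expr_ratio))
  cols <- grDevices::hcl.colors(length(er), "Dark 2")
  graphics::plot(range(x$affinity_ratio), c(0, max(x$overall) * 1.05),
                 type = "n", xlab = "affinity ratio (A : B)",
                 ylab = "overall in-silico coaggregation", ...)
  graphics::abline(h = 0.2, lty = 3)
  for (k in seq_along(er)) {
    sub <- x[x$expr_ratio == er[k], ]
    sub <- sub[order(sub$affinity_ratio), ]
    graphics::lines(sub$affinity_ratio, sub$overall, col = cols[k])
    graphics::points(sub$affinity_ratio, sub$overall, col = cols[k], pch = 16)
  }
  graphics::legend("topright", legend = paste0(er, ":1"), col = cols,
                   lty = 1, pch = 16, title = "expression", bty = "n")
  invisible(x)
}
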