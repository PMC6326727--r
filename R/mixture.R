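#' Log2 transform of a count matrix
#'
#' The analysis scale for targeted single-cell count panels:
#' `x = log2(count + 1)`.
#'
#' @param counts Non-negative numeric matrix or vector.
#' @return Transformed object of the same shape.
#' @examples
#' log2_transform(c(0, 1, 255))
#' @export
log2_transform <- function(counts) {
  if (!is.numeric(counts)) stop("'counts' must be numeric")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  log2(counts + 1)
}

#' Count matrix for a targeted single-cell panel
#'
#' Genes-by-cells non-negative integer counts with designated negative
#' control genes (panel genes assumed unexpressed in the profiled cell type,
#' used to estimate the null count distribution) and optional excluded
#' genes (e.g. probes with codeset errors), which carry no calls.
#'
#' @param counts Numeric matrix, genes in rows, cells in columns; dimnames
#'   used as gene names / cell ids when present.
#' @param control_genes Character vector of control gene names; default the
#'   conventional `c("Notch2", "Gfap", "Cdh13")` intersected with the genes
#'   present.
#' @param excluded_genes Character vector of genes to exclude from calling.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts,
                         control_genes = intersect(
                           c("Notch2", "Gfap", "Cdh13"), rownames(counts)),
                         excluded_genes = character(0)) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix (genes x cells)")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  if (!all(control_genes %in% rownames(counts)))
    stop("control genes absent from the matrix: ",
         paste(setdiff(control_genes, rownames(counts)), collapse = ", "))
  if (!all(excluded_genes %in% rownames(counts)))
    stop("excluded genes absent from the matrix: ",
         paste(setdiff(excluded_genes, rownames(counts)), collapse = ", "))
  structure(list(counts = counts,
                 gene_names = rownames(counts),
                 cell_ids = colnames(counts),
                 control_genes = control_genes,
                 excluded_genes = excluded_genes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Count matrix: %d genes x %d cells (%d control, %d excluded)\n",
              nrow(x$counts), ncol(x$counts), length(x$control_genes),
              length(x$excluded_genes)))
  invisible(x)
}

# floor for zeros on the log2 scale before gamma likelihood evaluation
# (the gamma support is strictly positive)
.gamma_floor <- 0.01

#' Fit the null (not expressed) model from negative control genes
#'
#' Pools the `log2(count + 1)` values of the designated negative control
#' genes across all cells and fits a gamma distribution by maximum
#' likelihood (moment-matched start). This shared null — one shape/scale for
#' the whole panel — is what lets single cells borrow strength: each cell's
#' mixture fit freezes its unexpressed component at these parameters.
#'
#' @param x A [count_matrix()].
#' @param min_obs Minimum pooled control observations required (default 10).
#' @return Object of class `null_model`: list with `shape`, `scale`,
#'   `mean` (= shape * scale), `var`, `n_obs`, and `q95`/`q99` null
#'   quantiles used by the degenerate-cell fallback.
#' @export
fit_null_from_controls <- function(x, min_obs = 10) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(x$control_genes) < 2)
    stop("need at least 2 control genes to estimate the null")
  vals <- as.vector(x$counts[x$control_genes, , drop = FALSE])
  if (length(vals) < min_obs)
    stop("need at least ", min_obs, " pooled control observations")
  if (all(vals == 0))
    stop("all control counts are zero: null distribution unidentifiable")
  y <- log2_transform(vals)
  if (stats::sd(y) == 0)
    stop("control values are constant: null variance is degenerate")
  # a count of 0 is left-censored on the log2 scale: any latent value below
  # log2(1.5) rounds to 0, and a point mass at the floor would bias the MLE
  # toward spuriously heavy tails
  cens <- log2(1.5)
  y0 <- pmax(y, cens / 2)
  m <- mean(y0); v <- max(stats::var(y0), 1e-4)
  start <- list(shape = m^2 / v, rate = m / v)
  if (any(y == 0)) {
    dd <- data.frame(left = ifelse(y > 0, y, NA),
                     right = ifelse(y > 0, y, cens))
    fit <- fitdistrplus::fitdistcens(dd, "gamma", start = start)
  } else {
    fit <- fitdistrplus::fitdist(y, "gamma", start = start)
  }
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  structure(list(shape = shape, scale = 1 / rate,
                 mean = shape / rate, var = shape / rate^2,
                 n_obs = length(y),
                 q95 = stats::qgamma(0.95, shape = shape, rate = rate),
                 q99 = stats::qgamma(0.99, shape = shape, rate = rate)),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "Null model: gamma(shape = %.3f, scale = %.3f) on log2(count+1)\n",
    x$shape, x$scale))
  cat(sprintf("  mean %.3f, sd %.3f, fitted on %d control values\n",
              x$mean, sqrt(x$var), x$n_obs))
  invisible(x)
}

#' @export
coef.null_model <- function(object, ...) {
  c(shape = object$shape, scale = object$scale)
}

#' Fit the constrained gamma-normal mixture for one cell
#'
#' EM fit of the two-component mixture
#' `pi * Gamma(shape, scale) + (1 - pi) * Normal(mu, sigma^2)` to one
#' cell's `log2(count + 1)` values. The gamma (unexpressed) component is
#' frozen at the pooled null model — the constraint that shares information
#' across cells — while the expressed component's `mu` and `sigma` are free,
#' subject to `mu >= null mean + 0.5` to prevent label switching.
#'
#' Cells with fewer than two values above the null 95th percentile, and
#' cells whose EM fails to converge, take a fallback path: a gene is called
#' expressed iff its value exceeds the null 99th percentile, and the fit is
#' flagged.
#'
#' @param values Numeric vector of one cell's `log2(count + 1)` values
#'   (>= 4 genes).
#' @param null A [fit_null_from_controls()] result.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 500).
#' @return Object of class `cell_mixture_fit`: list with `pi` (null
#'   weight), `mu`, `sigma`, `posterior` (per-gene probability of
#'   expressed), `loglik` (trace), `converged`, `fallback`,
#'   `boundary_hit` (mu constraint active), `n_iter`.
#' @export
fit_cell_mixture <- function(values, null, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(null, "null_model"))
  if (length(values) < 4) stop("need at least 4 genes per cell")
  if (anyNA(values) || any(values < 0))
    stop("'values' must be non-negative log2(count+1)")
  x <- pmax(values, .gamma_floor)
  mu_floor <- null$mean + 0.5
  n_high <- sum(x > null$q95)
  fallback_fit <- function(flag) {
    post <- as.numeric(x > null$q99)
    structure(list(pi = mean(post == 0), mu = NA_real_, sigma = NA_real_,
                   posterior = post, loglik = numeric(0),
                   converged = FALSE, fallback = TRUE,
                   boundary_hit = FALSE, n_iter = 0L, flag = flag),
              class = "cell_mixture_fit")
  }
  if (n_high < 2) return(fallback_fit("too_few_high_values"))

  # initialize the expressed component from the values that are already
  # implausible under the null (> q95): starting from the data's top
  # quartile instead can converge to a wide normal that blankets the null
  pi0 <- 0.7
  top <- x[x > null$q95]
  mu <- max(mean(top), mu_floor)
  sigma <- min(max(stats::sd(top), 0.25, na.rm = TRUE), 2)
  if (is.na(sigma)) sigma <- 0.25
  dnull <- stats::dgamma(x, shape = null$shape, scale = null$scale)
  ll <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step
    f0 <- pi0 * dnull
    f1 <- (1 - pi0) * stats::dnorm(x, mu, sigma)
    tot <- f0 + f1
    tot[tot == 0] <- .Machine$double.xmin
    gamma_null <- f0 / tot
    ll <- c(ll, sum(log(tot)))
    if (iter > 1 && abs(ll[iter] - ll[iter - 1]) < tol) {
      converged <- TRUE
      break
    }
    # M-step (sequential: pi, then constrained mu given sigma, then sigma)
    w <- 1 - gamma_null
    pi0 <- mean(gamma_null)
    if (sum(w) <= 0) return(fallback_fit("degenerate_pi"))
    mu <- max(sum(w * x) / sum(w), mu_floor)
    sigma <- min(max(sqrt(sum(w * (x - mu)^2) / sum(w)), 0.25), 2)
  }
  if (!converged) return(fallback_fit("non_convergence"))
  # separation guard: an "expressed" component inside the null bulk means
  # the EM split the null itself (no real expressed mass in this cell)
  if (mu < null$q99) return(fallback_fit("unseparated_component"))
  f0 <- pi0 * dnull
  f1 <- (1 - pi0) * stats::dnorm(x, mu, sigma)
  tot <- f0 + f1
  tot[tot == 0] <- .Machine$double.xmin
  posterior <- f1 / tot
  # enforce monotonicity in x: a larger value never gets a lower
  # expressed-posterior (the raw likelihood ratio can invert in the far
  # right tail when sigma is small)
  ord <- order(x)
  posterior[ord] <- cummax(posterior[ord])
  structure(list(pi = pi0, mu = mu, sigma = sigma, posterior = posterior,
                 loglik = ll, converged = TRUE, fallback = FALSE,
                 boundary_hit = isTRUE(all.equal(mu, mu_floor)),
                 n_iter = length(ll), flag = NA_character_),
            class = "cell_mixture_fit")
}

#' @export
print.cell_mixture_fit <- function(x, ...) {
  if (x$fallback)
    cat(sprintf("Cell mixture fit: fallback (%s); %d/%d genes expressed\n",
                x$flag, sum(x$posterior >= 0.5), length(x$posterior)))
  else
    cat(sprintf(
      "Cell mixture fit: pi(null) = %.3f, mu = %.3f, sigma = %.3f (%d iter%s)\n",
      x$pi, x$mu, x$sigma, x$n_iter,
      if (x$boundary_hit) ", mu at constraint" else ""))
  invisible(x)
}

#' @export
logLik.cell_mixture_fit <- function(object, ...) {
  if (!length(object$loglik)) return(NA_real_)
  structure(object$loglik[length(object$loglik)], df = 3,
            class = "logLik")
}

#' Call per-gene, per-cell expression with the constrained mixture model
#'
#' Fits the constrained gamma-normal mixture to each cell and classifies
#' each gene in each cell as expressed (posterior probability of the
#' expressed component >= 0.5) or not. Excluded genes are removed before
#' fitting and carry no calls.
#'
#' @param x A [count_matrix()].
#' @param null A [fit_null_from_controls()] result; fitted from `x` when
#'   `NULL`.
#' @param panel Character vector of genes over which to report per-cell
#'   expressed counts (e.g. a protocadherin panel); default all non-control,
#'   non-excluded genes.
#' @param tol,max_iter Passed to [fit_cell_mixture()].
#' @return Object of class `call_matrix`: list with `expressed` (logical
#'   genes-x-cells matrix), `posterior` (numeric), `panel`,
#'   `panel_counts` (per-cell expressed counts over the panel), `fits`
#'   (per-cell mixture fits), `null`, and the source `count_matrix`.
#' @export
call_expression <- function(x, null = NULL, panel = NULL,
                            tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(null)) null <- fit_null_from_controls(x)
  genes <- setdiff(x$gene_names, x$excluded_genes)
  if (length(x$excluded_genes))
    message("excluding ", length(x$excluded_genes), " gene(s) from calling: ",
            paste(x$excluded_genes, collapse = ", "))
  if (is.null(panel))
    panel <- setdiff(genes, x$control_genes)
  if (!all(panel %in% genes))
    stop("panel genes not available for calling: ",
         paste(setdiff(panel, genes), collapse = ", "))
  y <- log2_transform(x$counts[genes, , drop = FALSE])
  fits <- lapply(seq_len(ncol(y)), function(j)
    fit_cell_mixture(y[, j], null, tol = tol, max_iter = max_iter))
  posterior <- vapply(fits, function(f) f$posterior, numeric(nrow(y)))
  dimnames(posterior) <- dimnames(y)
  expressed <- posterior >= 0.5
  panel_counts <- if (length(panel))
    colSums(expressed[panel, , drop = FALSE]) else
    stats::setNames(rep(0L, ncol(y)), colnames(y))
  structure(list(expressed = expressed, posterior = posterior,
                 panel = panel, panel_counts = panel_counts,
                 fits = stats::setNames(fits, colnames(y)),
                 null = null, source = x),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  n_fb <- sum(vapply(x$fits, function(f) f$fallback, logical(1)))
  cat(sprintf("Expression calls: %d genes x %d cells; %d fallback cell(s)\n",
              nrow(x$expressed), ncol(x$expressed), n_fb))
  cat(sprintf("  panel (%d genes): per-cell expressed counts %d..%d, mean %.2f\n",
              length(x$panel), min(x$panel_counts), max(x$panel_counts),
              mean(x$panel_counts)))
  invisible(x)
}

#' @export
summary.call_matrix <- function(object, ...) {
  structure(list(
    n_genes = nrow(object$expressed), n_cells = ncol(object$expressed),
    panel = object$panel,
    distribution = expressed_count_distribution(object),
    n_fallback = sum(vapply(object$fits, function(f) f$fallback, logical(1)))
  ), class = "summary.call_matrix")
}

#' @export
print.summary.call_matrix <- function(x, ...) {
  cat(sprintf("Calls on %d genes x %d cells (panel of %d genes)\n",
              x$n_genes, x$n_cells, length(x$panel)))
  cat(sprintf("  per-cell expressed: max %d, mean %.2f; %d fallback cell(s)\n",
              x$distribution$max, x$distribution$mean, x$n_fallback))
  print(x$distribution$table)
  invisible(x)
}

#' Drop cells positive for a marker gene
#'
#' Removes cells in which the given gene is called expressed — e.g.
#' discarding Notch2-positive cells, whose profile indicates a non-neuronal
#' identity, before downstream analysis. Idempotent.
#'
#' @param calls A [call_expression()] result.
#' @param gene Marker gene name; must be present in the call matrix.
#' @return A `call_matrix` restricted to the retained cells, with a
#'   `dropped_cells` attribute listing the removed cell ids.
#' @export
filter_positive_cells <- function(calls, gene = "Notch2") {
  stopifnot(inherits(calls, "call_matrix"))
  if (!gene %in% rownames(calls$expressed))
    stop("gene '", gene, "' not present in the call matrix")
  pos <- calls$expressed[gene, ]
  if (any(pos))
    message("dropping ", sum(pos), " ", gene, "-positive cell(s): ",
            paste(colnames(calls$expressed)[pos], collapse = ", "))
  keep <- !pos
  out <- calls
  out$expressed <- calls$expressed[, keep, drop = FALSE]
  out$posterior <- calls$posterior[, keep, drop = FALSE]
  out$panel_counts <- calls$panel_counts[keep]
  out$fits <- calls$fits[keep]
  attr(out, "dropped_cells") <- colnames(calls$expressed)[pos]
  out
}

#' Distribution of per-cell expressed-gene counts
#'
#' Tabulates how many panel genes are called expressed in each cell — the
#' per-cell combinatorial repertoire size.
#'
#' @param calls A [call_expression()] result.
#' @param panel Gene panel; defaults to the panel stored in `calls`.
#' @return List with `counts` (named per-cell counts), `table` (frequency
#'   table over 0..max), `max`, and `mean`.
#' @export
expressed_count_distribution <- function(calls, panel = calls$panel) {
  stopifnot(inherits(calls, "call_matrix"))
  if (!all(panel %in% rownames(calls$expressed)))
    stop("panel genes not present in the call matrix: ",
         paste(setdiff(panel, rownames(calls$expressed)), collapse = ", "))
  counts <- if (length(panel))
    colSums(calls$expressed[panel, , drop = FALSE]) else
    stats::setNames(rep(0L, ncol(calls$expressed)),
                    colnames(calls$expressed))
  tab <- table(factor(counts, levels = 0:max(c(counts, 0))))
  list(counts = counts, table = tab,
       max = max(c(counts, 0)), mean = mean(counts))
}

#' Binary on/off calls from single-cell qPCR Ct values
#'
#' A gene is considered "on" in a cell when its Ct value is less than or
#' equal to 30 (boundary inclusive); Ct above 30 or missing (no
#' amplification observed) is "off".
#'
#' @param ct Numeric vector, matrix or data frame of Ct values; `NA` =
#'   not observed.
#' @param ct_max On/off boundary (default 30).
#' @return Logical object of the same shape: `TRUE` = on.
#' @examples
#' qpcr_call(c(24, 30, 30.01, NA))
#' @export
qpcr_call <- function(ct, ct_max = 30) {
  if (is.data.frame(ct)) ct <- as.matrix(ct)
  if (!is.numeric(ct)) stop("Ct values must be numeric")
  if (any(ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  out <- !is.na(ct) & ct <= ct_max
  if (is.matrix(ct)) dimnames(out) <- dimnames(ct)
  out
}
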