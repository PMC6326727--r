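#' Enumerate the ordered assays of a mismatch screen
#'
#' In a mismatch coaggregation screen, every assay mixes cells expressing
#' one family member X alone with cells co-expressing X plus a second
#' member Y. Every ordered pair (X, Y), X != Y, is a distinct assay, so n
#' members yield n(n-1) assays (42 for the 7 testable members).
#'
#' @param members Character vector of member names (>= 2, unique).
#' @return Data frame with columns `single` (X) and `partner` (Y).
#' @examples
#' nrow(enumerate_mismatch_pairs(paste0("Pcdh", c(1, 7, 9, 10, 17, 19, "11x"))))
#' @export
enumerate_mismatch_pairs <- function(members) {
  if (anyDuplicated(members)) stop("duplicate member names")
  if (length(members) < 2) {
    if (length(members) < 1) stop("need at least one member")
    return(data.frame(single = character(0), partner = character(0)))
  }
  grid <- expand.grid(partner = members, single = members,
                      stringsAsFactors = FALSE)[, 2:1]
  out <- grid[grid$single != grid$partner, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a mismatch screen into a CoAg matrix
#'
#' Builds the screen heat-map matrix M where `M[X, Y]` is the condition
#' mean CoAg of cells expressing X alone mixed with cells co-expressing
#' X + Y. Replicate values are averaged via [summarize_replicates()] (images
#' within a replicate first, then replicates). The diagonal (redundant
#' homophilic pairs) is undefined.
#'
#' @param assays Data frame with columns `single`, `partner`, `replicate`,
#'   `coag` (one row per image or per replicate mean).
#' @param members Member order for the matrix; default the sorted union of
#'   names seen.
#' @return Object of class `coag_matrix`: list with `M` (numeric matrix,
#'   `NA` diagonal and gaps), `sem` (matching SEM matrix), `n_replicates`,
#'   `members`.
#' @export
build_coag_matrix <- function(assays, members = NULL) {
  need <- c("single", "partner", "replicate", "coag")
  if (!all(need %in% names(assays)))
    stop("'assays' must have columns ", paste(need, collapse = ", "))
  if (any(assays$coag < 0 | assays$coag > 1))
    stop("CoAg values must lie in [0, 1]")
  if (any(assays$single == assays$partner))
    stop("homophilic (diagonal) assays are redundant and not allowed")
  if (is.null(members))
    members <- sort(unique(c(assays$single, assays$partner)))
  n <- length(members)
  M <- sem <- matrix(NA_real_, n, n, dimnames = list(members, members))
  nrep <- matrix(0L, n, n, dimnames = list(members, members))
  key <- interaction(assays$single, assays$partner, drop = TRUE)
  for (grp in split(assays, key)) {
    s <- summarize_replicates(grp$coag, grp$replicate,
                              condition = paste0(grp$single[1], " vs ",
                                                 grp$single[1], "+",
                                                 grp$partner[1]))
    M[grp$single[1], grp$partner[1]] <- s$mean
    sem[grp$single[1], grp$partner[1]] <- s$sem
    nrep[grp$single[1], grp$partner[1]] <- s$n_replicates
  }
  missing <- sum(is.na(M)) - n
  if (missing > 0)
    warning(missing, " assay cell(s) have no data; left as gaps")
  structure(list(M = M, sem = sem, n_replicates = nrep, members = members),
            class = "coag_matrix")
}

#' @export
print.coag_matrix <- function(x, ...) {
  cat(sprintf("Mismatch screen: %d members, %d/%d assay cells measured\n",
              length(x$members),
              sum(!is.na(x$M)),
              length(x$members) * (length(x$members) - 1L)))
  print(round(x$M, 3))
  invisible(x)
}

#' Heat map of a mismatch screen matrix
#'
#' Rows are the single-expressing populations, columns the co-expressed
#' partner; the diagonal (redundant homophilic pairs) is blank.
#'
#' @param x A [build_coag_matrix()] result.
#' @param ... Passed to [graphics::image()].
#' @export
plot.coag_matrix <- function(x, ...) {
  n <- length(x$members)
  z <- t(x$M[n:1, , drop = FALSE])
  graphics::image(seq_len(n), seq_len(n), z, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "co-expressed partner (column)",
                  ylab = "single population (row)", ...)
  graphics::axis(1, seq_len(n), x$members, las = 2)
  graphics::axis(2, seq_len(n), rev(x$members), las = 2)
  graphics::box()
  invisible(x)
}

#' Net mismatch scores from a screen matrix
#'
#' Summarizes each member's ability to overcome a mismatch and still
#' coaggregate: `score(X) = mean over available partners Y of
#' (M[X, Y] - M[Y, X])` — how much better X intermixes into its mismatch
#' pairs than its partners intermix into theirs. On a complete matrix the
#' scores sum to zero. Gaps are tolerated pairwise-complete; a member with
#' no measured partner in both directions gets an undefined score and is
#' flagged.
#'
#' Note this antisymmetric row-minus-transposed-column mean is this
#' package's definition of the score; it reproduces the intended
#' qualitative behaviour (strong intermixers score high, strong segregators
#' low) and is invariant to adding a constant to every matrix entry.
#'
#' @param x A [build_coag_matrix()] result (or a plain numeric matrix with
#'   dimnames).
#' @return Object of class `net_mismatch_scores`: list with `scores`
#'   (named, ranking order: descending score, ties alphabetical),
#'   `n_partners`, `undefined` (members with no usable partner).
#' @export
net_mismatch_score <- function(x) {
  M <- if (inherits(x, "coag_matrix")) x$M else as.matrix(x)
  if (nrow(M) != ncol(M) || is.null(rownames(M)))
    stop("need a square matrix with member names")
  if (nrow(M) < 2) stop("need at least 2 members")
  members <- rownames(M)
  D <- M - t(M)                       # antisymmetric where both measured
  diag(D) <- NA
  score <- rowMeans(D, na.rm = TRUE)
  n_partners <- rowSums(!is.na(D))
  score[n_partners == 0] <- NA_real_
  undefined <- members[n_partners == 0]
  if (length(undefined))
    warning("no usable partners for: ", paste(undefined, collapse = ", "))
  ord <- order(-score, members, na.last = TRUE)
  structure(list(scores = score[ord], n_partners = n_partners[ord],
                 undefined = undefined),
            class = "net_mismatch_scores")
}

#' @export
print.net_mismatch_scores <- function(x, ...) {
  cat("Net mismatch scores (descending):\n")
  for (m in names(x$scores))
    cat(sprintf("  %-10s %+.4f  (%d partner%s)\n", m, x$scores[m],
                x$n_partners[m], if (x$n_partners[m] == 1) "" else "s"))
  invisible(x)
}

#' Regress mean CoAg on the number of co-expressed members
#'
#' Ordinary least squares of condition-mean CoAg values against the number
#' of additional co-expressed family members, quantifying how each added
#' member dilutes the focal member's coaggregation.
#'
#' @param n_coexpressed Numeric predictor (>= 3 distinct points required
#'   overall, non-degenerate).
#' @param mean_coag Response values.
#' @return List with `slope`, `intercept`, `r_squared`, and the underlying
#'   `lm` fit.
#' @examples
#' regress_coag_vs_n(1:3, c(0.4, 0.3, 0.2))
#' @export
regress_coag_vs_n <- function(n_coexpressed, mean_coag) {
  if (length(n_coexpressed) != length(mean_coag))
    stop("inputs must have equal length")
  if (length(n_coexpressed) < 3) stop("need at least 3 points")
  if (stats::var(n_coexpressed) == 0)
    stop("degenerate predictor: all x values equal")
  fit <- stats::lm(mean_coag ~ n_coexpressed)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((mean_coag - mean(mean_coag))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - rss / tss,
       fit = fit)
}
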