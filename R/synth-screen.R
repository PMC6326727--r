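#' Generate a synthetic mismatch screen with planted asymmetry
#'
#' Builds replicate-level CoAg values for every ordered assay (X single vs
#' X + Y co-expressing) with a known additive dominance structure:
#' `CoAg[X, Y] = base + effect[X] - effect[Y] + noise`, clipped to
#' \[0, 1\]. Members with larger effects overcome their mismatches and
#' intermix (high row values), so the planted net-mismatch ranking is the
#' ranking of `effects`. With symmetric (equal) effects and zero noise all
#' net mismatch scores are exactly 0.
#'
#' @param members Character vector of member names (>= 2).
#' @param effects Named numeric dominance effects, one per member; default
#'   all zero (symmetric screen).
#' @param base Baseline CoAg of a balanced mismatch (default 0.15,
#'   interface regime).
#' @param noise_sd SD of additive replicate noise (default 0.02).
#' @param n_replicates Replicates per assay.
#' @param seed Integer seed.
#' @return List with `assays` (data frame `single`, `partner`,
#'   `replicate`, `coag` ready for [build_coag_matrix()]) and `truth`
#'   (list: `effects`, `expected_mean` matrix without noise/clipping,
#'   `ranking` — members by descending effect, ties alphabetical).
#' @export
make_screen_matrix <- function(members = paste0("Pcdh",
                                                c(1, 7, 9, 10, 17, 19, "11x")),
                               effects = NULL, base = 0.15, noise_sd = 0.02,
                               n_replicates = 3, seed = 1) {
  if (length(members) < 2) stop("need at least 2 members")
  if (anyDuplicated(members)) stop("duplicate member names")
  if (is.null(effects))
    effects <- stats::setNames(rep(0, length(members)), members)
  if (!all(members %in% names(effects)))
    stop("'effects' must name every member")
  effects <- effects[members]
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  withr::local_seed(seed)
  pairs <- enumerate_mismatch_pairs(members)
  expected <- base + effects[pairs$single] - effects[pairs$partner]
  if (any(expected < 0 | expected > 1))
    warning("planted means leave [0, 1]; values are clipped")
  assays <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(single = pairs$single, partner = pairs$partner,
               replicate = r,
               coag = pmin(pmax(expected +
                                  stats::rnorm(nrow(pairs), 0, noise_sd),
                                0), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(assays) <- NULL
  n <- length(members)
  E <- matrix(NA_real_, n, n, dimnames = list(members, members))
  E[cbind(pairs$single, pairs$partner)] <- pmin(pmax(expected, 0), 1)
  ranking <- members[order(-effects, members)]
  list(assays = assays,
       truth = list(effects = effects, expected_mean = E, ranking = ranking))
}
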