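#' Write / read a count matrix as CSV
#'
#' Counts are stored genes-as-rows, cells-as-columns with the gene name in
#' the first column; control and excluded genes are recorded in a sidecar
#' CSV `<path>.genes.csv` with columns `gene`, `role`.
#'
#' @param x A [count_matrix()].
#' @param path Output CSV path.
#' @return `write_count_csv` returns `path` invisibly; `read_count_csv`
#'   returns a [count_matrix()].
#' @export
write_count_csv <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = x$gene_names, x$counts, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  role <- ifelse(x$gene_names %in% x$control_genes, "control",
                 ifelse(x$gene_names %in% x$excluded_genes, "excluded",
                        "target"))
  utils::write.csv(data.frame(gene = x$gene_names, role = role),
                   paste0(path, ".genes.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_csv
#' @param sep Field separator (`","` for CSV, `"\t"` for TSV).
#' @export
read_count_csv <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  sidecar <- paste0(path, ".genes.csv")
  control <- character(0); excluded <- character(0)
  if (file.exists(sidecar)) {
    roles <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    control <- roles$gene[roles$role == "control"]
    excluded <- roles$gene[roles$role == "excluded"]
  } else {
    control <- intersect(c("Notch2", "Gfap", "Cdh13"), rownames(counts))
  }
  count_matrix(counts, control_genes = control, excluded_genes = excluded)
}

#' Tabulate CoAg results across images
#'
#' Collects per-image [compute_coag()] results into the flat table written
#' alongside a screen or condition series.
#'
#' @param results List of `coag_result` objects.
#' @param image Image identifiers (default sequential).
#' @param condition,replicate Optional grouping labels, recycled.
#' @return Data frame with columns `image`, `condition`, `replicate`,
#'   `n_occupied`, `n_multicolor`, `coag`, `behavior`.
#' @export
coag_table <- function(results, image = seq_along(results),
                       condition = NA, replicate = NA) {
  stopifnot(all(vapply(results, inherits, logical(1), "coag_result")))
  data.frame(
    image = image,
    condition = rep_len(condition, length(results)),
    replicate = rep_len(replicate, length(results)),
    n_occupied = vapply(results, `[[`, numeric(1), "n_occupied"),
    n_multicolor = vapply(results, `[[`, numeric(1), "n_multicolor"),
    coag = vapply(results, `[[`, numeric(1), "coag"),
    behavior = vapply(results, `[[`, character(1), "behavior"),
    stringsAsFactors = FALSE
  )
}
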