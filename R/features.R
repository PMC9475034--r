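#' Construct a network feature table
#'
#' Per-patient network features: a numeric matrix plus per-column metadata
#' tags of the form `centrality:<name>` or
#' `modularity:<algorithm>:<module-index>` (optionally prefixed by an
#' omics provenance label after fusion).
#'
#' @param values Patients-by-features numeric matrix with patient IDs as
#'   rownames.
#' @param column_meta Character vector of per-column tags, one per column.
#' @return An object of class `network_features`.
#' @export
network_features <- function(values, column_meta) {
  stopifnot(is.matrix(values), length(column_meta) == ncol(values))
  if (is.null(rownames(values))) stop("values must carry patient IDs as rownames")
  colnames(values) <- make.unique(column_meta, sep = "#")
  structure(list(values = values, column_meta = column_meta),
            class = "network_features")
}

#' @export
print.network_features <- function(x, ...) {
  n_cent <- sum(startsWith(x$column_meta, "centrality"))
  cat(sprintf("<network_features: %d patients x %d columns (%d centrality, %d modularity)>\n",
              nrow(x$values), ncol(x$values), n_cent, ncol(x$values) - n_cent))
  invisible(x)
}

#' Assemble centrality and modularity features of a PSN
#'
#' Concatenates the 13-column centrality block (see
#' [compute_centralities()]) with one-hot module-membership blocks from
#' spectral clustering and the weighted stochastic block model, each with
#' its own silhouette-selected module count. Every patient therefore
#' contributes 13 centrality values plus exactly two 1s across the
#' modularity columns (one per clustering algorithm).
#'
#' @param g A [psn] or fused affinity.
#' @param k_grid Candidate module counts passed to
#'   [select_k_by_silhouette()]; `NULL` for the default grid.
#' @param seed Integer seed for the clustering restarts.
#' @param algorithms Clustering algorithms contributing modularity blocks.
#' @return A [network_features] table of width `13 + k_spectral + k_sbm`
#'   with attributes `k_spectral` / `k_sbm` recording the selected counts.
#' @export
assemble_features <- function(g, k_grid = NULL, seed = 1,
                              algorithms = c("spectral", "sbm")) {
  cent <- compute_centralities(g)
  blocks <- list(cent)
  meta <- paste0("centrality:", CENTRALITY_NAMES)
  ks <- list()
  for (alg in algorithms) {
    sel <- select_k_by_silhouette(g, algorithm = alg, k_grid = k_grid, seed = seed)
    blocks <- c(blocks, list(encode_membership(sel$labels, sel$k)))
    meta <- c(meta, sprintf("modularity:%s:%d", alg, seq_len(sel$k) - 1L))
    ks[[alg]] <- sel$k
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- rownames(cent)
  out <- network_features(values, meta)
  attr(out, "k_spectral") <- ks[["spectral"]]
  attr(out, "k_sbm") <- ks[["sbm"]]
  out
}

#' Z-score feature columns
#'
#' Centers and scales columns to zero mean and unit variance. When
#' `center`/`scale` statistics are supplied (e.g. fitted on a training
#' fold) they are applied instead of being re-estimated, which keeps test
#' folds untouched by their own statistics. Constant columns get unit
#' scale.
#'
#' @param x Numeric matrix or [network_features].
#' @param center,scale Optional per-column statistics to apply.
#' @return Matrix of the same shape with attributes `center` and `scale`.
#' @export
zscore_features <- function(x, center = NULL, scale = NULL) {
  vals <- if (inherits(x, "network_features")) x$values else x
  if (is.null(center)) center <- colMeans(vals)
  if (is.null(scale)) {
    scale <- apply(vals, 2L, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  out <- sweep(sweep(vals, 2L, center, "-"), 2L, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Write / read a network feature table as TSV
#'
#' Column metadata tags are used as the header; patient IDs form the
#' first column.
#'
#' @param x A [network_features].
#' @param path TSV path.
#' @return `write_features` invisibly returns `path`; `read_features`
#'   returns a [network_features].
#' @export
write_features <- function(x, path) {
  df <- data.frame(patient_id = rownames(x$values), x$values,
                   check.names = FALSE)
  colnames(df) <- c("patient_id", x$column_meta)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- as.character(df[[1L]])
  meta <- colnames(df)[-1L]
  network_features(vals, meta)
}
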