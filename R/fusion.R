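#' Full transition kernel of a similarity matrix
#'
#' Row-normalizes an affinity into the SNF "full" kernel:
#' `P(i,j) = a(i,j) / (2 * sum_{k != i} a(i,k))` off the diagonal and
#' `P(i,i) = 1/2`, so every row sums to 1 and half of each patient's mass
#' stays on itself (numerical stabilization of the diffusion).
#'
#' @param a Symmetric nonnegative affinity matrix with zero diagonal.
#' @return Row-stochastic matrix of the same dimension.
#' @export
snf_full_kernel <- function(a) {
  rs <- rowSums(a) - diag(a)
  if (any(rs <= 0)) {
    ids <- rownames(a) %||% as.character(seq_len(nrow(a)))
    stop("all-zero affinity row(s) for patient(s): ",
         paste(ids[rs <= 0], collapse = ", "))
  }
  P <- a / (2 * rs)
  diag(P) <- 1 / 2
  P
}

#' Local (K-nearest-neighbor) kernel of a similarity matrix
#'
#' For each row keeps the `K` largest off-diagonal affinities (ties broken
#' toward the lower patient index), renormalizes the kept entries to sum
#' to 1, and zeroes everything else. This sparse kernel restricts the SNF
#' diffusion to each patient's local neighborhood.
#'
#' @param a Symmetric nonnegative affinity matrix with zero diagonal.
#' @param K Neighborhood size, `1 <= K <= n - 1`.
#' @return Row-stochastic sparse (many zeros) matrix.
#' @export
snf_local_kernel <- function(a, K) {
  n <- nrow(a)
  if (K < 1 || K > n - 1) stop_param("K", "must satisfy 1 <= K <= n - 1")
  S <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    row <- a[i, ]
    row[i] <- -Inf
    keep <- order(row, decreasing = TRUE)[seq_len(K)]  # stable: ties -> lower index
    kept <- a[i, keep]
    tot <- sum(kept)
    S[i, keep] <- if (tot > 0) kept / tot else 1 / K
  }
  S
}

#' Similarity network fusion of per-omics patient networks
#'
#' Cross-diffusion in the style of similarity network fusion: each
#' source's full kernel is repeatedly updated as
#' `P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)` (with the half-diagonal
#' row normalization of [snf_full_kernel()] restored after every step),
#' diffusing each network's similarity mass through its
#' own K-nearest-neighbor topology while averaging the others' global
#' structure. After `t` iterations the final kernels are averaged and
#' symmetrized; the diagonal is zeroed for downstream PSN use.
#'
#' @param affinities List of two or more symmetric nonnegative affinity
#'   matrices with identical patient ordering (e.g. `$affinity` of per-omics
#'   [psn]s, or the psn objects themselves).
#' @param K Neighborhood size of the local kernel
#'   (default `min(20, n - 1)`).
#' @param t Number of cross-diffusion iterations (default 20).
#' @return A `fused_affinity` object: `affinity` (symmetric, nonnegative,
#'   zero diagonal), `source_names`, `snf_params`.
#' @export
snf_fuse <- function(affinities, K = NULL, t = 20) {
  mats <- lapply(affinities, as_affinity)
  if (length(mats) < 2L) stop("need at least 2 affinity matrices to fuse")
  n <- nrow(mats[[1L]])
  ids <- rownames(mats[[1L]])
  for (m in mats) {
    if (nrow(m) != n || ncol(m) != n) stop("affinity shape mismatch across sources")
    if (!is.null(ids) && !is.null(rownames(m)) && !identical(rownames(m), ids)) {
      stop("patient ordering differs across sources")
    }
  }
  K <- K %||% min(20L, n - 1L)
  if (K < 1 || K > n - 1) stop_param("K", "must satisfy 1 <= K <= n - 1")
  src_names <- vapply(seq_along(affinities), function(i) {
    x <- affinities[[i]]
    if (inherits(x, "psn")) x$omics_name else sprintf("source%d", i)
  }, character(1))

  P <- lapply(mats, snf_full_kernel)
  S <- lapply(mats, snf_local_kernel, K = K)
  M <- length(mats)
  for (iter in seq_len(t)) {
    P_new <- vector("list", M)
    for (v in seq_len(M)) {
      others <- Reduce(`+`, P[-v]) / (M - 1)
      upd <- S[[v]] %*% others %*% t(S[[v]])
      # restore the half-diagonal row normalization after each diffusion
      rs <- rowSums(upd) - diag(upd)
      upd <- upd / (2 * rs)
      diag(upd) <- 1 / 2
      P_new[[v]] <- upd
    }
    P <- P_new
  }
  fused <- Reduce(`+`, P) / M
  fused <- (fused + t(fused)) / 2
  diag(fused) <- 0
  dimnames(fused) <- dimnames(mats[[1L]])
  structure(list(affinity = fused, source_names = src_names,
                 snf_params = list(K = K, t = t)),
            class = "fused_affinity")
}

#' @export
print.fused_affinity <- function(x, ...) {
  cat(sprintf("<fused_affinity: %d patients from %s (K = %d, t = %d)>\n",
              nrow(x$affinity), paste(x$source_names, collapse = " + "),
              x$snf_params$K, x$snf_params$t))
  invisible(x)
}

#' Convert a fused affinity to a PSN
#'
#' Rescales the fused affinity by its maximum entry so weights lie in
#' `[0, 1]` (affinity rank order is unchanged).
#'
#' @param x A `fused_affinity`.
#' @return A [psn] with `omics_name` concatenating the sources.
#' @export
as_psn <- function(x) {
  stopifnot(inherits(x, "fused_affinity"))
  aff <- x$affinity
  mx <- max(aff)
  if (mx > 0) aff <- aff / mx
  psn(aff, omics_name = paste(x$source_names, collapse = "+"))
}

#' Feature-level fusion of per-omics network feature tables
#'
#' Combines per-omics [network_features] tables into one multi-omics
#' table: the 13-column centrality blocks are averaged elementwise across
#' omics, and the modularity one-hot blocks are concatenated in input
#' order with provenance-tagged column metadata.
#'
#' @param tables List of [network_features], identical patient ordering,
#'   each starting with the standard 13-column centrality block.
#' @param names Optional provenance labels, one per table.
#' @return A [network_features] of width `13 + sum(modularity widths)`.
#' @export
fuse_feature_level <- function(tables, names = NULL) {
  stopifnot(length(tables) >= 2L)
  names <- names %||% sprintf("omics%d", seq_along(tables))
  ids <- rownames(tables[[1L]]$values)
  cent_meta <- paste0("centrality:", CENTRALITY_NAMES)
  cent_blocks <- list()
  mod_blocks <- list()
  mod_meta <- character(0)
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    if (!identical(rownames(tb$values), ids)) {
      stop("patient ordering differs across feature tables")
    }
    is_cent <- startsWith(tb$column_meta, "centrality:")
    if (!identical(tb$column_meta[is_cent], cent_meta)) {
      stop("each table must start with the standard 13-column centrality block")
    }
    cent_blocks[[i]] <- tb$values[, is_cent, drop = FALSE]
    mod_blocks[[i]] <- tb$values[, !is_cent, drop = FALSE]
    mod_meta <- c(mod_meta, paste0(names[i], ":", tb$column_meta[!is_cent]))
  }
  cent <- Reduce(`+`, cent_blocks) / length(cent_blocks)
  values <- cbind(cent, do.call(cbind, mod_blocks))
  rownames(values) <- ids
  network_features(values, c(cent_meta, mod_meta))
}
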