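#' Construct a patient similarity network object
#'
#' A PSN is a complete weighted graph on the patients: a symmetric
#' nonnegative affinity matrix with zero diagonal and entries in `[0, 1]`,
#' together with the soft-threshold power used to build it and the
#' scale-free fit achieved at that power.
#'
#' @param affinity Symmetric numeric matrix with patient IDs as dimnames.
#' @param beta Soft-threshold power (NA if the affinity was not built by
#'   soft thresholding, e.g. a fused network).
#' @param fit_r2 Scale-free fit index at `beta`.
#' @param omics_name Label of the source omics.
#' @return An object of class `psn`.
#' @export
psn <- function(affinity, beta = NA_real_, fit_r2 = NA_real_,
                omics_name = "omics") {
  stopifnot(is.matrix(affinity), is.numeric(affinity),
            nrow(affinity) == ncol(affinity))
  if (is.null(rownames(affinity))) {
    rownames(affinity) <- colnames(affinity) <- sprintf("P%03d", seq_len(nrow(affinity)))
  }
  if (max(abs(affinity - t(affinity))) > 1e-10) {
    stop("affinity must be symmetric within 1e-10")
  }
  if (any(abs(diag(affinity)) > 1e-12)) stop("affinity diagonal must be zero")
  if (min(affinity) < -1e-12 || max(affinity) > 1 + 1e-12) {
    stop("affinity entries must lie in [0, 1]")
  }
  affinity <- (affinity + t(affinity)) / 2
  diag(affinity) <- 0
  structure(list(affinity = affinity, beta = beta, fit_r2 = fit_r2,
                 omics_name = omics_name),
            class = "psn")
}

#' @export
print.psn <- function(x, ...) {
  cat(sprintf("<psn '%s': %d patients, beta = %s, scale-free fit R2 = %s>\n",
              x$omics_name, nrow(x$affinity),
              format(x$beta), format(round(x$fit_r2, 3))))
  invisible(x)
}

#' Pairwise Pearson correlation between patient profiles
#'
#' Correlates every pair of patients across the features of one omics
#' matrix. This inter-patient correlation is the similarity measure from
#' which the PSN is built.
#'
#' @param x An [omics_matrix].
#' @return Symmetric patients-by-patients matrix in `[-1, 1]` with unit
#'   diagonal.
#' @export
patient_correlation <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  vals <- x$values
  if (ncol(vals) < 2L) stop("need at least 2 features to correlate patients")
  sds <- apply(vals, 1L, sd)
  if (any(sds == 0)) {
    stop("zero-variance patient profile(s): ",
         paste(rownames(vals)[sds == 0], collapse = ", "))
  }
  r <- cor(t(vals))
  # numerical guard: cor can exceed |1| by ~1e-16
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Soft-threshold a correlation matrix into edge weights
#'
#' Applies the signed weighted-network rescaling
#' `a_uv = ((1 + r_uv) / 2)^beta`, mapping correlations from `[-1, 1]` to
#' nonnegative weights in `[0, 1]` and suppressing weak similarities as
#' `beta` grows. The diagonal is zeroed (no self-similarity).
#'
#' @param corr Symmetric correlation matrix in `[-1, 1]`.
#' @param beta Integer power `>= 1`.
#' @return Affinity matrix of the same dimension.
#' @export
soft_threshold <- function(corr, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 1) {
    stop_param("beta", "must be a single power >= 1")
  }
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit index of a weighted network
#'
#' Measures how closely the connectivity distribution follows a truncated
#' power law. Node connectivities `k_u = sum_v a_uv` are binned into
#' `n_bins` equal-width bins; the log10 bin frequency is regressed on
#' log10 mean bin connectivity plus a linear (truncation) term in the
#' connectivity itself. Returns the regression R-squared when the log-k
#' slope is negative (a decaying tail), and 0 otherwise or when fewer than
#' 3 bins are occupied.
#'
#' @param affinity Symmetric nonnegative affinity matrix, or a weighted
#'   `igraph` graph.
#' @param n_bins Number of equal-width connectivity bins (default 10).
#' @return Fit index in `[0, 1]`.
#' @export
scale_free_fit_index <- function(affinity, n_bins = 10) {
  if (inherits(affinity, "igraph")) {
    k <- igraph::strength(affinity)
  } else if (inherits(affinity, "psn")) {
    k <- rowSums(affinity$affinity)
  } else {
    k <- rowSums(affinity)
  }
  rng <- range(k)
  if (diff(rng) < 1e-12) return(0)  # degenerate: all connectivities equal
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  occupied <- counts > 0L
  if (sum(occupied) < 3L) return(0)
  k_mean <- tapply(k, bin, mean)[occupied]
  freq <- counts[occupied] / length(k)
  fit <- stats::lm(log10(freq) ~ log10(k_mean) + k_mean)
  slope <- coef(fit)[["log10(k_mean)"]]
  if (!is.finite(slope) || slope >= 0) return(0)
  r2 <- summary(fit)$r.squared
  if (!is.finite(r2)) 0 else r2
}

#' Select the soft-threshold power for scale-free topology
#'
#' Scans an ascending grid of powers and returns the smallest whose
#' soft-thresholded affinity reaches the target scale-free fit. If no
#' power qualifies, the grid argmax of the fit index is returned with a
#' warning.
#'
#' @param corr Symmetric correlation matrix.
#' @param target_r2 Required fit index (default 0.9).
#' @param beta_grid Ascending integer powers to scan (default `1:20`).
#' @param n_bins Bins for [scale_free_fit_index()].
#' @return List with `beta`, `fit_r2`, and the full `scan` (data.frame of
#'   beta vs fit).
#' @export
select_soft_threshold <- function(corr, target_r2 = 0.9, beta_grid = 1:20,
                                  n_bins = 10) {
  if (length(beta_grid) < 1L || is.unsorted(beta_grid)) {
    stop_param("beta_grid", "must be a nonempty ascending vector")
  }
  if (target_r2 <= 0 || target_r2 > 1) {
    stop_param("target_r2", "must lie in (0, 1]")
  }
  fits <- numeric(length(beta_grid))
  for (i in seq_along(beta_grid)) {
    fits[i] <- scale_free_fit_index(soft_threshold(corr, beta_grid[i]), n_bins)
    if (fits[i] >= target_r2) {
      return(list(beta = beta_grid[i], fit_r2 = fits[i],
                  scan = data.frame(beta = beta_grid[seq_len(i)],
                                    fit_r2 = fits[seq_len(i)])))
    }
  }
  best <- which.max(fits)
  warning(sprintf(
    "no power in the grid reached fit %.2f; returning argmax beta = %d (fit %.3f)",
    target_r2, beta_grid[best], fits[best]))
  list(beta = beta_grid[best], fit_r2 = fits[best],
       scan = data.frame(beta = beta_grid, fit_r2 = fits))
}

#' Build a patient similarity network from one omics matrix
#'
#' Composes [patient_correlation()], [select_soft_threshold()] and
#' [soft_threshold()]: inter-patient Pearson correlations are rescaled to
#' positive edge weights with the smallest power whose connectivity
#' distribution reaches the target scale-free fit. The complete weighted
#' graph is kept (no hard sparsification), so current-flow centralities
#' remain well defined downstream.
#'
#' @param x An [omics_matrix] (already cleaned/prefiltered).
#' @param target_r2 Target scale-free fit index (default 0.9).
#' @param beta_grid Powers to scan (default `1:20`).
#' @param n_bins Connectivity bins for the fit index.
#' @return A [psn] with `beta` and `fit_r2` recorded.
#' @export
build_psn <- function(x, target_r2 = 0.9, beta_grid = 1:20, n_bins = 10) {
  corr <- patient_correlation(x)
  sel <- select_soft_threshold(corr, target_r2 = target_r2,
                               beta_grid = beta_grid, n_bins = n_bins)
  aff <- soft_threshold(corr, sel$beta)
  psn(aff, beta = sel$beta, fit_r2 = sel$fit_r2, omics_name = x$omics_name)
}

#' Write / read a PSN as TSV plus sidecar metadata
#'
#' The affinity is stored as a symmetric TSV matrix with a patient-ID
#' header column, and `beta`, `fit_r2`, `omics_name` go to a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param g A [psn].
#' @param path Output TSV path.
#' @return `write_psn` invisibly returns `path`; `read_psn` returns a
#'   [psn].
#' @export
write_psn <- function(g, path) {
  df <- data.frame(patient_id = patient_ids(g), g$affinity, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(beta = g$beta, fit_r2 = g$fit_r2, omics_name = g$omics_name),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_psn
#' @export
read_psn <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  aff <- as.matrix(df[, -1L, drop = FALSE])
  rownames(aff) <- as.character(df[[1L]])
  aff <- (aff + t(aff)) / 2  # absorb text round-trip asymmetry
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  psn(aff, beta = meta$beta %||% NA_real_, fit_r2 = meta$fit_r2 %||% NA_real_,
      omics_name = meta$omics_name %||% "omics")
}
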