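#' Construct an omics matrix
#'
#' Thin container for one omics type's measurements: a numeric
#' patients-by-features matrix with unique patient and feature identifiers
#' held as dimnames, plus an omics label.
#'
#' @param values Numeric matrix, patients in rows, features in columns,
#'   with complete dimnames.
#' @param omics_name Label for the omics type.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, omics_name = "omics") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry patient IDs as rownames and feature IDs as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("patient IDs must be unique")
  if (anyDuplicated(colnames(values))) stop("feature IDs must be unique")
  if (anyNA(values)) stop("omics matrix contains missing values")
  if (ncol(values) < 2L) stop("an omics matrix needs at least 2 features")
  structure(list(values = values, omics_name = omics_name),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s': %d patients x %d features>\n",
              x$omics_name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Patient identifiers of an omics object
#' @param x An `omics_matrix`, `psn` or `network_features` object.
#' @return Character vector of patient IDs in stored order.
#' @export
patient_ids <- function(x) {
  if (inherits(x, "omics_matrix")) return(rownames(x$values))
  if (inherits(x, "psn")) return(rownames(x$affinity))
  if (inherits(x, "network_features")) return(rownames(x$values))
  if (inherits(x, "fused_affinity")) return(rownames(x$affinity))
  stop("no patient IDs for objects of class ", paste(class(x), collapse = "/"))
}

#' Load an omics matrix from delimited text
#'
#' Reads a TSV/CSV with a header row and an identifier first column, and
#' applies the standard cleaning rules: features containing any missing
#' value are dropped; duplicate patient or feature identifiers keep the
#' first occurrence. Drop counts are reported via `message()`.
#'
#' @param path Path to the delimited file.
#' @param orientation `"patients_rows"` (default) if rows are patients, or
#'   `"features_rows"` if the file stores features as rows (the matrix is
#'   transposed to patients-by-features internally).
#' @param sep Field separator; defaults to tab, use `","` for CSV.
#' @param omics_name Label for the omics type; defaults to the file name.
#' @return An [omics_matrix].
#' @export
load_omics_matrix <- function(path, orientation = c("patients_rows", "features_rows"),
                              sep = "\t", omics_name = NULL) {
  orientation <- match.arg(orientation)
  omics_name <- omics_name %||% sub("\\.[^.]*$", "", basename(path))
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("empty-data error: file has no value columns: ", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      suppressWarnings(num <- as.numeric(body[[j]]))
      bad <- which(is.na(num) & !is.na(body[[j]]) & body[[j]] != "NA")
      if (length(bad)) {
        stop(sprintf("parse error: non-numeric cell at row %d, column '%s' in %s",
                     bad[1L], colnames(body)[j], path))
      }
      body[[j]] <- num
    }
  }
  values <- as.matrix(body)
  rownames(values) <- ids
  if (orientation == "features_rows") values <- t(values)

  dup_p <- duplicated(rownames(values))
  if (any(dup_p)) {
    message(sprintf("dropped %d duplicate patient ID(s) (first kept)", sum(dup_p)))
    values <- values[!dup_p, , drop = FALSE]
  }
  dup_f <- duplicated(colnames(values))
  if (any(dup_f)) {
    message(sprintf("dropped %d duplicate feature ID(s) (first kept)", sum(dup_f)))
    values <- values[, !dup_f, drop = FALSE]
  }
  has_na <- colSums(is.na(values)) > 0L
  if (any(has_na)) {
    message(sprintf("dropped %d feature(s) containing missing values", sum(has_na)))
    values <- values[, !has_na, drop = FALSE]
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty-data error: no patients or features remain after cleaning: ", path)
  }
  omics_matrix(values, omics_name = omics_name)
}

#' Load outcome labels from a two-column TSV
#'
#' @param path TSV with columns `patient_id` and `label` (0/1).
#' @param sep Field separator.
#' @return Named integer vector of 0/1 labels.
#' @export
load_labels <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  labels <- as.integer(df[[2L]])
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  names(labels) <- as.character(df[[1L]])
  labels
}

#' Univariate rank-test feature prefilter
#'
#' Screens features one at a time with a two-sample Mann-Whitney rank-sum
#' test (normal approximation with tie correction) of the class-0 versus
#' class-1 value distributions, adjusts all p-values by Benjamini-Hochberg,
#' and keeps the features whose adjusted p-value falls below `alpha`.
#' High-dimensional omics matrices carry mostly outcome-irrelevant
#' features; this filter removes them before network construction.
#'
#' @param x An [omics_matrix].
#' @param labels Binary 0/1 labels; if named, they are aligned to
#'   `patient_ids(x)`, otherwise positional order is assumed.
#' @param alpha Significance level applied to BH-adjusted p-values
#'   (default 0.001).
#' @return An [omics_matrix] restricted to the retained features (input
#'   column order preserved), with attributes `p_adjusted` (named vector
#'   over all input features) and `kept` (logical vector).
#' @export
filter_features_ranktest <- function(x, labels, alpha = 0.001) {
  stopifnot(inherits(x, "omics_matrix"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop_param("alpha", "must lie in (0, 1]")
  }
  labels <- align_labels(labels, patient_ids(x))
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be non-empty for the rank test")
  }
  vals <- x$values
  g0 <- labels == 0L
  pvals <- vapply(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    if (length(unique(v)) == 1L) return(1)  # no rank separation possible
    suppressWarnings(
      wilcox.test(v[g0], v[!g0], exact = FALSE, correct = FALSE)$p.value
    )
  }, numeric(1))
  pvals[is.na(pvals)] <- 1
  padj <- p.adjust(pvals, method = "BH")
  names(padj) <- colnames(vals)
  kept <- if (alpha >= 1) rep(TRUE, length(padj)) else padj < alpha
  if (!any(kept)) {
    stop(sprintf(
      "empty-result error: no feature passed the BH-adjusted threshold %g; try a larger alpha",
      alpha))
  }
  out <- omics_matrix(vals[, kept, drop = FALSE], omics_name = x$omics_name)
  attr(out, "p_adjusted") <- padj
  attr(out, "kept") <- unname(kept)
  out
}

# Align a label vector to an ID ordering; errors on mismatch.
align_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    if (!all(ids %in% names(labels))) {
      stop("labels are missing for some patient IDs")
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("labels length does not match number of patients")
  }
  lab <- as.integer(labels)
  if (anyNA(lab) || !all(lab %in% c(0L, 1L))) stop("labels must be binary 0/1")
  names(lab) <- ids
  lab
}
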