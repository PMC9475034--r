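#' Specification for a synthetic multi-omics cohort
#'
#' Describes a cohort of `n_patients` with one numeric feature matrix per
#' omics type, a binary outcome label (1 = event, e.g. death from disease;
#' 0 = no event), and a planted class signal in a known subset of features.
#' Two signal modes are supported: `"heterogeneous"` draws an independent
#' informative signal per omics (distinct molecular layers, e.g. expression
#' and methylation), while `"homogeneous"` re-measures one shared latent
#' signal in every omics with independent measurement noise (two platforms
#' assaying the same transcriptome).
#'
#' @param n_patients Number of patients.
#' @param dims Integer vector, number of features per omics type.
#' @param n_informative Integer vector (recycled to `length(dims)`), number
#'   of informative features per omics. Must not exceed the matching `dims`.
#' @param effect_size Standardized mean shift, in units of `noise_sd`,
#'   added to informative features of class-1 patients.
#' @param imbalance Fraction of patients in the majority (label 0) class;
#'   must lie in `(0.5, 1)`. Label counts are fixed by rounding, so the
#'   realized split is exact, not stochastic.
#' @param mode `"heterogeneous"` or `"homogeneous"` (see Details).
#' @param noise_sd Standard deviation of the background Gaussian noise.
#' @param measurement_sd_frac In homogeneous mode, the per-omics measurement
#'   noise SD as a fraction of `noise_sd`.
#' @param seed Integer seed; required, the generator keeps no global RNG
#'   state and identical specs yield bit-identical cohorts.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_multiomics()]
#' @export
synthetic_spec <- function(n_patients, dims, n_informative,
                           effect_size = 1, imbalance = 0.77,
                           mode = c("heterogeneous", "homogeneous"),
                           noise_sd = 1, measurement_sd_frac = 0.5,
                           seed) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop_param("seed", "an integer seed is required")
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 2) {
    stop_param("n_patients", "must be a single count >= 2")
  }
  if (!is.numeric(dims) || length(dims) < 1L || any(dims < 1)) {
    stop_param("dims", "must be a nonempty vector of positive feature counts")
  }
  n_informative <- rep_len(as.integer(n_informative), length(dims))
  if (any(n_informative < 0) || any(n_informative > dims)) {
    stop_param("n_informative", "must satisfy 0 <= n_informative <= dims per omics")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0) {
    stop_param("effect_size", "must be a single nonnegative number")
  }
  if (!is.numeric(imbalance) || length(imbalance) != 1L ||
      imbalance <= 0.5 || imbalance >= 1) {
    stop_param("imbalance", "must lie strictly between 0.5 and 1")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop_param("noise_sd", "must be a single positive number")
  }
  structure(
    list(n_patients = as.integer(n_patients), dims = as.integer(dims),
         n_informative = n_informative, effect_size = effect_size,
         imbalance = imbalance, mode = mode, noise_sd = noise_sd,
         measurement_sd_frac = measurement_sd_frac,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic multi-omics cohort with planted class signal
#'
#' Draws one patients-by-features Gaussian matrix per omics type plus binary
#' outcome labels. Background features are i.i.d. `N(0, noise_sd^2)`.
#' Informative features of class-1 patients have their mean shifted by
#' `effect_size * noise_sd`, with the direction of each feature's shift
#' drawn once at random (differential features are a mix of up- and
#' down-regulated ones, which also keeps the class signal visible to
#' mean-invariant similarity measures such as inter-patient correlation).
#' In homogeneous mode the informative signal is a
#' single shared latent matrix re-observed by every omics with independent
#' measurement noise; in heterogeneous mode each omics draws its own
#' independent informative signal.
#'
#' Label counts are exact: `round(imbalance * n_patients)` patients receive
#' the majority label 0 and the rest label 1; which patients are in which
#' class is randomized under the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{matrices}{list of [omics_matrix] objects, one per entry of
#'       `spec$dims`, sharing patient IDs in identical order.}
#'     \item{labels}{named integer vector of 0/1 outcomes, names are
#'       patient IDs.}
#'     \item{informative}{list of integer vectors, the planted informative
#'       feature indices per omics (ground truth for recovery tests).}
#'   }
#' @examples
#' sp <- synthetic_spec(60, dims = c(100, 80), n_informative = 10,
#'                      effect_size = 1.5, imbalance = 0.6, seed = 1)
#' cohort <- generate_multiomics(sp)
#' table(cohort$labels)
#' @export
generate_multiomics <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop_param("spec", "must be a `synthetic_spec` object")
  }
  n <- spec$n_patients
  n_major <- as.integer(round(spec$imbalance * n))
  n_minor <- n - n_major
  if (n_minor < 1L) stop_param("imbalance", "leaves the minority class empty")
  patient_ids <- sprintf("P%03d", seq_len(n))
  shift <- spec$effect_size * spec$noise_sd

  with_seed(spec$seed, {
    labels <- integer(n)
    labels[sample.int(n, n_minor)] <- 1L
    names(labels) <- patient_ids

    n_shared <- max(spec$n_informative)
    latent <- NULL
    shared_signs <- NULL
    if (spec$mode == "homogeneous" && n_shared > 0L) {
      # one shared signal matrix, re-measured by every omics; each feature
      # is up- or down-shifted in class 1 (mixed regulation directions)
      shared_signs <- sample(c(-1, 1), n_shared, replace = TRUE)
      latent <- matrix(rnorm(n * n_shared, sd = spec$noise_sd), n, n_shared) +
        outer(labels, shared_signs) * shift
    }

    matrices <- vector("list", length(spec$dims))
    informative <- vector("list", length(spec$dims))
    for (m in seq_along(spec$dims)) {
      p <- spec$dims[m]
      k <- spec$n_informative[m]
      values <- matrix(rnorm(n * p, sd = spec$noise_sd), n, p)
      idx <- if (k > 0L) sort(sample.int(p, k)) else integer(0)
      if (k > 0L) {
        if (spec$mode == "homogeneous") {
          meas <- matrix(rnorm(n * k, sd = spec$noise_sd * spec$measurement_sd_frac),
                         n, k)
          values[, idx] <- latent[, seq_len(k), drop = FALSE] + meas
        } else {
          signs <- sample(c(-1, 1), k, replace = TRUE)
          values[, idx] <- values[, idx, drop = FALSE] +
            outer(labels, signs) * shift
        }
      }
      dimnames(values) <- list(patient_ids, sprintf("om%d_f%04d", m, seq_len(p)))
      matrices[[m]] <- omics_matrix(values, omics_name = sprintf("omics%d", m))
      informative[[m]] <- idx
    }
    list(matrices = matrices, labels = labels, informative = informative)
  })
}

#' Generate a preferential-attachment benchmark graph
#'
#' Grows a connected undirected graph by preferential attachment
#' (Barabasi-Albert) with unit edge weights. Its heavy-tailed degree
#' distribution makes it the reference fixture for the scale-free fit
#' index used in soft-threshold selection.
#'
#' @param n Number of nodes.
#' @param m_edges Edges added by each incoming node; `1 <= m_edges < n`.
#' @param seed Integer seed.
#' @return An `igraph` graph with a `weight` edge attribute of 1s.
#' @export
generate_pa_graph <- function(n, m_edges, seed) {
  if (!is.numeric(m_edges) || m_edges < 1 || m_edges >= n) {
    stop_param("m_edges", "must satisfy 1 <= m_edges < n")
  }
  g <- with_seed(seed, igraph::sample_pa(n, m = m_edges, directed = FALSE))
  igraph::E(g)$weight <- 1
  g
}

#' Generate a planted-block affinity matrix
#'
#' Builds a symmetric patients-by-patients affinity with `within` affinity
#' inside planted blocks and `between` across blocks, plus truncated
#' Gaussian jitter. Used as ground truth for module-recovery tests.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param within,between Mean affinity inside / across blocks.
#' @param noise_sd SD of symmetric jitter added to off-diagonal entries.
#' @param seed Integer seed.
#' @return List with `affinity` (symmetric matrix, zero diagonal, entries
#'   clipped to `[0, 1]`) and `labels` (planted block index per node,
#'   0-based).
#' @export
generate_block_affinity <- function(block_sizes, within = 0.9, between = 0.1,
                                    noise_sd = 0.02, seed = 1) {
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes) - 1L, block_sizes)
  base <- ifelse(outer(labels, labels, "=="), within, between)
  with_seed(seed, {
    jit <- matrix(rnorm(n * n, sd = noise_sd), n, n)
    jit <- (jit + t(jit)) / 2
    aff <- pmin(pmax(base + jit, 0), 1)
    diag(aff) <- 0
    rownames(aff) <- colnames(aff) <- sprintf("P%03d", seq_len(n))
    list(affinity = aff, labels = labels)
  })
}

#' Write a synthetic cohort to TSV files
#'
#' Writes each omics matrix as a TSV (patients as rows, first column
#' `patient_id`, remaining columns features) plus a two-column labels TSV
#' (`patient_id`, `label`).
#'
#' @param cohort Result of [generate_multiomics()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_multiomics <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (om in cohort$matrices) {
    df <- data.frame(patient_id = patient_ids(om), om$values,
                     check.names = FALSE)
    f <- file.path(dir, paste0(om$omics_name, ".tsv"))
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  lf <- file.path(dir, "labels.tsv")
  write.table(data.frame(patient_id = names(cohort$labels),
                         label = unname(cohort$labels)),
              lf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, lf))
}
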