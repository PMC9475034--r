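# Spectral embedding: rows of the k leading eigenvectors of the
# symmetric-normalized affinity D^{-1/2} W D^{-1/2}, row-normalized
# (Ng-Jordan-Weiss). Equivalent to the k smallest eigenvalues of the
# symmetric-normalized Laplacian.
spectral_embedding <- function(W, k) {
  d <- rowSums(W)
  d[d <= 0] <- 1e-12
  Dh <- 1 / sqrt(d)
  M <- Dh * sweep(W, 2L, Dh, "*")
  es <- eigen(M, symmetric = TRUE)
  U <- es$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U / norms
}

#' Spectral clustering of a patient similarity network
#'
#' Normalized spectral clustering: the affinity's symmetric-normalized
#' Laplacian is eigendecomposed, the rows of the `k` leading eigenvectors
#' are unit-normalized, and k-means (10 restarts, fixed seed) assigns hard
#' module labels.
#'
#' @param g A [psn], fused affinity, or affinity matrix.
#' @param k Number of modules, `2 <= k <= n - 1`.
#' @param seed Integer seed for the k-means restarts.
#' @return Integer vector of 0-based module labels, length `n`.
#' @export
spectral_modules <- function(g, k, seed = 1) {
  W <- as_affinity(g)
  n <- nrow(W)
  if (k < 2 || k > n - 1) stop_param("k", "must satisfy 2 <= k <= n - 1")
  emb <- spectral_embedding(W, k)
  km <- with_seed(seed, kmeans(emb, centers = k, nstart = 10, iter.max = 100))
  as.integer(km$cluster) - 1L
}

#' Weighted stochastic block model clustering
#'
#' Fits a Gaussian-weight stochastic block model by greedy single-node
#' label moves that maximize the block log-likelihood (equivalently,
#' minimize the within/between block sum of squared weight deviations
#' from the block-pair means), starting from the spectral clustering
#' partition. Moves that would empty a block are disallowed, so exactly
#' `k` modules are returned.
#'
#' @inheritParams spectral_modules
#' @return Integer vector of 0-based module labels.
#' @export
sbm_modules <- function(g, k, seed = 1) {
  W <- as_affinity(g)
  n <- nrow(W)
  if (k < 2 || k > n - 1) stop_param("k", "must satisfy 2 <= k <= n - 1")
  labels <- spectral_modules(W, k, seed = seed) + 1L
  sbm_greedy(W, labels, k) - 1L
}

# Greedy ascent on the Gaussian-SBM objective Q = sum_{a<=b} S_ab^2 / N_ab
# (total log-likelihood = const - SSE, SSE = sum w^2 - Q).
sbm_greedy <- function(W, labels, k, max_passes = 50) {
  n <- nrow(W)
  sizes <- tabulate(labels, nbins = k)
  # block-pair weight sums, S[a,b]; diagonal holds within-block pair sums
  S <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in a:k) {
      if (a == b) {
        sub <- W[labels == a, labels == a, drop = FALSE]
        S[a, a] <- sum(sub) / 2
      } else {
        S[a, b] <- S[b, a] <- sum(W[labels == a, labels == b, drop = FALSE])
      }
    }
  }
  # Q contribution of rows a and c of the block-sum matrix (the only terms
  # a single a -> c move can change); the shared (a, c) term is counted once.
  rows_q <- function(row_a, row_c, a, cc, sza, szc, sz) {
    Na <- sza * sz; Na[a] <- sza * (sza - 1) / 2; Na[cc] <- sza * szc
    Nc <- szc * sz; Nc[cc] <- szc * (szc - 1) / 2; Nc[a] <- sza * szc
    qa <- ifelse(Na > 0, row_a^2 / Na, 0)
    qc <- ifelse(Nc > 0, row_c^2 / Nc, 0)
    sum(qa) + sum(qc) - qc[a]
  }
  # Rows a and c after moving node v (with block weight-sums sv) from a to c.
  moved_rows <- function(S, a, cc, sv) {
    row_a <- S[a, ] - sv
    row_c <- S[cc, ] + sv
    row_a[a] <- S[a, a] - sv[a]
    row_a[cc] <- S[a, cc] + sv[a] - sv[cc]
    row_c[cc] <- S[cc, cc] + sv[cc]
    row_c[a] <- row_a[cc]
    list(a = row_a, c = row_c)
  }
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (v in seq_len(n)) {
      a <- labels[v]
      if (sizes[a] <= 1L) next  # would empty block a
      sv <- as.numeric(rowsum(W[v, ], labels, reorder = TRUE))
      if (length(sv) < k) {  # rowsum drops absent groups; cannot happen here
        sv <- vapply(seq_len(k), function(b) sum(W[v, labels == b]), numeric(1))
      }
      # sv[a] excludes v itself since W[v, v] = 0
      best_gain <- 1e-12
      best_c <- 0L
      for (cc in seq_len(k)) {
        if (cc == a) next
        nr <- moved_rows(S, a, cc, sv)
        gain <- rows_q(nr$a, nr$c, a, cc, sizes[a] - 1, sizes[cc] + 1,
                       sizes + (seq_len(k) == cc) - (seq_len(k) == a)) -
          rows_q(S[a, ], S[cc, ], a, cc, sizes[a], sizes[cc], sizes)
        if (gain > best_gain) {
          best_gain <- gain
          best_c <- cc
        }
      }
      if (best_c > 0L) {
        cc <- best_c
        nr <- moved_rows(S, a, cc, sv)
        S[a, ] <- nr$a; S[, a] <- nr$a
        S[cc, ] <- nr$c; S[, cc] <- nr$c
        S[a, a] <- nr$a[a]; S[cc, cc] <- nr$c[cc]
        S[a, cc] <- S[cc, a] <- nr$a[cc]
        sizes[a] <- sizes[a] - 1L
        sizes[cc] <- sizes[cc] + 1L
        labels[v] <- cc
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  labels
}

# Gaussian-SBM log-likelihood (up to constants): -SSE of weights around
# their block-pair means. Exposed for the ascent-property check.
sbm_log_likelihood <- function(W, labels) {
  labels <- as.integer(labels)
  blocks <- sort(unique(labels))
  sse <- 0
  for (ai in seq_along(blocks)) {
    for (bi in ai:length(blocks)) {
      a <- blocks[ai]; b <- blocks[bi]
      ia <- which(labels == a); ib <- which(labels == b)
      if (a == b) {
        if (length(ia) < 2) next
        sub <- W[ia, ia]
        w <- sub[upper.tri(sub)]
      } else {
        w <- as.numeric(W[ia, ib])
      }
      if (length(w) > 0) sse <- sse + sum((w - mean(w))^2)
    }
  }
  -sse
}

#' Mean silhouette width of a partition on the spectral embedding
#'
#' @param W Affinity matrix.
#' @param labels 0-based module labels.
#' @param k Number of modules used for the embedding dimension.
#' @return Mean silhouette width (Euclidean distance on the k-dimensional
#'   spectral embedding); `-1` if fewer than 2 distinct labels.
#' @keywords internal
silhouette_on_embedding <- function(W, labels, k) {
  if (length(unique(labels)) < 2L) return(-1)
  emb <- spectral_embedding(W, k)
  mean_silhouette(emb, labels)
}

# Plain mean silhouette width with Euclidean distances.
mean_silhouette <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  labs <- unique(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(labs[labs != labels[i]], function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of modules by silhouette score
#'
#' Clusters the PSN for each candidate `k`, scores the partition by mean
#' silhouette width on the spectral embedding, and returns the `k`
#' maximizing the silhouette (ties broken toward the smallest `k`). The
#' default grid is geometric (`2, 4, 8, ...` up to `n/2`) refined by
#' `k - 1` and `k + 1` around the best candidate, so large module counts
#' stay reachable at modest cost.
#'
#' @param g A [psn], fused affinity, or affinity matrix.
#' @param algorithm `"spectral"` or `"sbm"`.
#' @param k_grid Candidate module counts; `NULL` for the default geometric
#'   grid.
#' @param seed Integer seed.
#' @return List with `k` (selected count), `labels` (0-based), and `scan`
#'   (data.frame of k vs silhouette).
#' @export
select_k_by_silhouette <- function(g, algorithm = c("spectral", "sbm"),
                                   k_grid = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  W <- as_affinity(g)
  n <- nrow(W)
  refine <- is.null(k_grid)
  if (is.null(k_grid)) {
    k_grid <- unique(pmin(2^(1:20), floor(n / 2)))
    k_grid <- k_grid[k_grid >= 2 & k_grid <= n - 1]
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0L || any(k_grid < 2) || any(k_grid > n - 1)) {
    stop_param("k_grid", "must be a nonempty subset of [2, n - 1]")
  }
  cluster_fn <- if (algorithm == "spectral") spectral_modules else sbm_modules
  score_k <- function(k) {
    labels <- cluster_fn(W, k, seed = seed)
    list(labels = labels, sil = silhouette_on_embedding(W, labels, k))
  }
  res <- lapply(k_grid, score_k)
  sils <- vapply(res, `[[`, numeric(1), "sil")
  best <- which.max(sils)  # first max -> smallest k on ties
  if (refine) {
    extra <- setdiff(intersect(c(k_grid[best] - 1L, k_grid[best] + 1L), 2:(n - 1)),
                     k_grid)
    for (k in extra) {
      r <- score_k(k)
      k_grid <- c(k_grid, k)
      res <- c(res, list(r))
      sils <- c(sils, r$sil)
    }
    ord <- order(k_grid)
    k_grid <- k_grid[ord]; res <- res[ord]; sils <- sils[ord]
    best <- which.max(sils)
  }
  list(k = k_grid[best], labels = res[[best]]$labels,
       scan = data.frame(k = k_grid, silhouette = sils))
}

#' One-hot encode module membership
#'
#' @param labels Integer labels in `0..k-1`.
#' @param k Number of modules (columns).
#' @return `length(labels)` by `k` 0/1 matrix; row `v` has a single 1 in
#'   column `labels[v] + 1`.
#' @export
encode_membership <- function(labels, k) {
  labels <- as.integer(labels)
  if (any(labels < 0L) || any(labels >= k)) {
    stop("labels must lie in 0..k-1")
  }
  M <- matrix(0, length(labels), k)
  M[cbind(seq_along(labels), labels + 1L)] <- 1
  M
}
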