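# Small named graphs used by the closed-form centrality checks ------------

affinity_K4 <- function() {
  W <- matrix(1, 4, 4); diag(W) <- 0
  dimnames(W) <- list(paste0("P", 1:4), paste0("P", 1:4))
  W
}

affinity_P3 <- function() {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  dimnames(W) <- list(paste0("P", 1:3), paste0("P", 1:3))
  W
}

# Star: node 1 is the hub, nodes 2..(n_leaves+1) are leaves.
affinity_star <- function(n_leaves = 4) {
  n <- n_leaves + 1L
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- 1
  dimnames(W) <- list(paste0("P", 1:n), paste0("P", 1:n))
  W
}

# Random symmetric connected weighted affinity (complete graph).
random_affinity <- function(n, seed) {
  withr::with_seed(seed, {
    W <- matrix(runif(n * n, 0.05, 1), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    dimnames(W) <- list(paste0("P", seq_len(n)), paste0("P", seq_len(n)))
    W
  })
}

# Independent oracles -----------------------------------------------------

# Adjusted Rand index between two partitions (contingency-table formula).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Onnela weighted local clustering by explicit triple loop.
onnela_oracle <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  C <- numeric(n)
  if (mx <= 0) return(C)
  Wh <- (W / mx)^(1 / 3)
  for (u in seq_len(n)) {
    nb <- which(W[u, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (v in nb) for (w in nb) if (v != w) s <- s + Wh[u, v] * Wh[v, w] * Wh[w, u]
    C[u] <- s / (k * (k - 1))
  }
  C
}

# Brute-force minimum-peeling: recompute the base measure from scratch on
# every residual subgraph, remove the minimum attainers, record values.
peel_oracle <- function(W, base = c("weighted_degree", "clustering")) {
  base <- match.arg(base)
  base_fn <- function(sub) {
    if (base == "weighted_degree") apply(sub, 1, sum) else onnela_oracle(sub)
  }
  n <- nrow(W)
  score <- numeric(n)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    idx <- which(alive)
    vals <- base_fn(W[idx, idx, drop = FALSE])
    at_min <- vals <= min(vals) + 1e-12
    score[idx[at_min]] <- vals[at_min]
    alive[idx[at_min]] <- FALSE
  }
  score
}

# Straight-line SNF: explicit loops over the full kernel, the top-K local
# kernel, and the cross-diffusion update, written independently of the
# package implementation.
snf_oracle <- function(mats, K, t) {
  n <- nrow(mats[[1]])
  full_k <- function(a) {
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
      s <- sum(a[i, -i])
      for (j in seq_len(n)) {
        P[i, j] <- if (i == j) 0.5 else a[i, j] / (2 * s)
      }
    }
    P
  }
  local_k <- function(a) {
    S <- matrix(0, n, n)
    for (i in seq_len(n)) {
      row <- a[i, ]
      row[i] <- -Inf
      keep <- order(row, decreasing = TRUE)[seq_len(K)]
      S[i, keep] <- a[i, keep] / sum(a[i, keep])
    }
    S
  }
  P <- lapply(mats, full_k)
  S <- lapply(mats, local_k)
  M <- length(mats)
  for (it in seq_len(t)) {
    P_new <- P
    for (v in seq_len(M)) {
      avg <- matrix(0, n, n)
      for (u in seq_len(M)) if (u != v) avg <- avg + P[[u]]
      avg <- avg / (M - 1)
      upd <- S[[v]] %*% avg %*% t(S[[v]])
      for (i in seq_len(n)) {
        s <- sum(upd[i, -i])
        upd[i, ] <- upd[i, ] / (2 * s)
        upd[i, i] <- 0.5
      }
      P_new[[v]] <- upd
    }
    P <- P_new
  }
  fused <- Reduce(`+`, P) / M
  fused <- (fused + t(fused)) / 2
  diag(fused) <- 0
  fused
}

# Current-flow betweenness by direct per-pair potential loops.
cfb_oracle <- function(W) {
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  Linv <- solve(L + 1 / n) - 1 / n
  out <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      p <- Linv[, s] - Linv[, t]
      for (v in setdiff(seq_len(n), c(s, t))) {
        out[v] <- out[v] + 0.5 * sum(W[v, ] * abs(p[v] - p))
      }
    }
  }
  out / ((n - 1) * (n - 2) / 2)
}

# Shared synthetic fixtures ------------------------------------------------

# Two-omics heterogeneous cohort used by the pipeline-level checks.
hetero_cohort <- function(n = 150, seed = 42) {
  generate_multiomics(synthetic_spec(
    n_patients = n, dims = c(500, 400), n_informative = 50,
    effect_size = 2, imbalance = 0.55, mode = "heterogeneous", seed = seed))
}
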