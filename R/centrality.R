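# Canonical order of the 13 centrality columns.
CENTRALITY_NAMES <- c(
  "weighted_degree", "closeness", "cf_closeness", "cf_betweenness",
  "eigenvector", "katz", "hits_authority", "hits_hub", "pagerank",
  "load", "clustering", "iter_weighted_degree", "iter_clustering"
)

# Extract the affinity matrix from a psn / fused_affinity / plain matrix.
as_affinity <- function(g) {
  if (inherits(g, "psn") || inherits(g, "fused_affinity")) return(g$affinity)
  if (inherits(g, "igraph")) {
    return(as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)))
  }
  stopifnot(is.matrix(g), nrow(g) == ncol(g))
  g
}

affinity_to_igraph <- function(W, distances = FALSE) {
  A <- W
  if (distances) {
    A[W > 0] <- 1 / W[W > 0]
  }
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Node centrality features of a patient similarity network
#'
#' Computes the 13 centrality columns used as per-patient network
#' features, in this fixed order: weighted degree; closeness;
#' current-flow closeness; current-flow betweenness; eigenvector; Katz;
#' HITS authority; HITS hub; PageRank; load; local clustering
#' coefficient; iterative weighted degree; iterative local clustering
#' coefficient.
#'
#' Shortest-path measures (closeness, load) use edge length `1/weight`;
#' current-flow measures treat weights as conductances (Laplacian
#' pseudoinverse); spectral measures (eigenvector, Katz, HITS) act on the
#' weight matrix itself. Local clustering uses the Onnela geometric-mean
#' weighted form. The iterative variants come from the minimum-peeling
#' scheme of [iterative_measure()].
#'
#' @param g A [psn], fused affinity, weighted `igraph` graph, or plain
#'   symmetric affinity matrix.
#' @return Patients-by-13 numeric matrix with columns named as above.
#' @export
compute_centralities <- function(g) {
  W <- as_affinity(g)
  n <- nrow(W)
  if (n < 3L) stop("centralities need at least 3 nodes")
  ig <- affinity_to_igraph(W)
  comp <- igraph::components(ig)
  if (comp$no > 1L) {
    stop(sprintf("graph is disconnected (%d components; sizes %s)",
                 comp$no, paste(comp$csize, collapse = ", ")))
  }
  ig_d <- affinity_to_igraph(W, distances = TRUE)
  dists <- igraph::distances(ig_d)

  out <- matrix(NA_real_, n, length(CENTRALITY_NAMES),
                dimnames = list(rownames(W), CENTRALITY_NAMES))
  out[, "weighted_degree"] <- rowSums(W)
  out[, "closeness"] <- (n - 1) / rowSums(dists)

  # current-flow measures from the Laplacian pseudoinverse
  L <- diag(rowSums(W)) - W
  Linv <- solve(L + 1 / n) - 1 / n
  res_dist <- outer(diag(Linv), diag(Linv), "+") - 2 * Linv
  out[, "cf_closeness"] <- (n - 1) / rowSums(res_dist)
  out[, "cf_betweenness"] <- cfb_from_linv(W, Linv)

  es <- eigen(W, symmetric = TRUE)
  v1 <- abs(es$vectors[, 1L])
  out[, "eigenvector"] <- v1 / max(v1)
  lambda1 <- es$values[1L]
  alpha <- 0.9 / lambda1
  katz <- solve(diag(n) - alpha * W, rep(1, n))
  out[, "katz"] <- katz / sqrt(sum(katz^2))
  auth <- v1 / sum(v1)  # HITS on an undirected graph: principal eigenvector of W^2
  out[, "hits_authority"] <- auth
  out[, "hits_hub"] <- auth
  out[, "pagerank"] <- igraph::page_rank(ig, weights = igraph::E(ig)$weight)$vector
  btw <- igraph::betweenness(ig_d, weights = igraph::E(ig_d)$weight)
  out[, "load"] <- btw * 2 / ((n - 1) * (n - 2))
  out[, "clustering"] <- onnela_clustering(W)
  out[, "iter_weighted_degree"] <- iterative_measure(W, "weighted_degree")
  out[, "iter_clustering"] <- iterative_measure(W, "clustering")
  out
}

# Onnela geometric-mean weighted local clustering coefficient.
onnela_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx <= 0) return(rep(0, n))
  Wh <- (W / mx)^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  cc <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  as.numeric(cc)
}

#' Iterative (peeling) node measures
#'
#' Generalizes k-core ranking to weighted measures: repeatedly compute the
#' base measure on the remaining subgraph, record the current value for
#' the node(s) attaining the minimum, remove them, and repeat until the
#' graph is empty. A node's iterative score is its base value at the
#' moment of its removal, so nodes surviving deep into the peeling are
#' scored on progressively denser residual cores.
#'
#' @param g A [psn], weighted `igraph`, or affinity matrix.
#' @param base `"weighted_degree"` or `"clustering"` (Onnela weighted
#'   local clustering coefficient).
#' @return Numeric per-node score in input node order.
#' @export
iterative_measure <- function(g, base = c("weighted_degree", "clustering")) {
  base <- match.arg(base)
  W <- as_affinity(g)
  n <- nrow(W)
  score <- numeric(n)
  remaining <- seq_len(n)
  measure <- function(sub) {
    if (base == "weighted_degree") rowSums(sub) else onnela_clustering(sub)
  }
  while (length(remaining) > 0L) {
    sub <- W[remaining, remaining, drop = FALSE]
    vals <- measure(sub)
    mn <- min(vals)
    at_min <- which(vals <= mn + 1e-12)
    score[remaining[at_min]] <- vals[at_min]
    remaining <- remaining[-at_min]
  }
  score
}
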