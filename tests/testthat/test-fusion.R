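test_that("full kernel matches the closed-form normalization", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(snf_full_kernel(W), matrix(0.5, 2, 2))
  # 3-node asymmetric-mass example, evaluated by hand:
  # row 1 mass = 1 + 2 = 3 -> off-diagonal 1/6, 2/6
  A <- matrix(c(0, 1, 2,
                1, 0, 4,
                2, 4, 0), 3, 3, byrow = TRUE)
  P <- snf_full_kernel(A)
  expect_equal(P[1, ], c(0.5, 1 / 6, 2 / 6))
  expect_equal(P[2, ], c(1 / 10, 0.5, 4 / 10))
  expect_equal(unname(rowSums(P)), rep(1, 3))
  bad <- matrix(0, 3, 3); bad[1, 2] <- bad[2, 1] <- 1
  rownames(bad) <- colnames(bad) <- c("a", "b", "lonely")
  expect_error(snf_full_kernel(bad), "lonely")
})

test_that("local kernel keeps the top-K neighbors with deterministic ties", {
  A <- matrix(c(0, 3, 1, 2,
                3, 0, 2, 2,
                1, 2, 0, 4,
                2, 2, 4, 0), 4, 4, byrow = TRUE)
  S1 <- snf_local_kernel(A, 1)
  expect_equal(S1[1, ], c(0, 1, 0, 0))      # strongest neighbor only
  expect_equal(S1[2, ], c(1, 0, 0, 0))
  S2 <- snf_local_kernel(A, 2)
  # row 2 has a tie (2, 2) after the top entry 3: lower index kept
  expect_equal(S2[2, ], c(3 / 5, 0, 2 / 5, 0))
  expect_equal(unname(rowSums(S2)), rep(1, 4))
  S3 <- snf_local_kernel(A, 3)
  expect_true(all(S3[upper.tri(S3) | lower.tri(S3)] > 0))
  expect_error(snf_local_kernel(A, 0), "K")
  expect_error(snf_local_kernel(A, 4), "K")
})

test_that("top-K selection matches a brute-force sort oracle", {
  for (seed in 1:3) {
    A <- random_affinity(9, 60 + seed)
    for (K in c(2, 5)) {
      S <- snf_local_kernel(A, K)
      for (i in 1:9) {
        kept <- which(S[i, ] > 0)
        oracle <- order(replace(A[i, ], i, -Inf), decreasing = TRUE)[1:K]
        expect_setequal(kept, oracle)
      }
    }
  }
})

test_that("cross-diffusion matches a straight-line oracle on a seeded instance", {
  mats <- list(random_affinity(4, 71), random_affinity(4, 72))
  fused <- snf_fuse(mats, K = 3, t = 2)
  expect_lt(max(abs(fused$affinity - snf_oracle(mats, K = 3, t = 2))), 1e-10)
  # a second configuration, three sources
  mats3 <- list(random_affinity(6, 73), random_affinity(6, 74),
                random_affinity(6, 75))
  fused3 <- snf_fuse(mats3, K = 4, t = 3)
  expect_lt(max(abs(fused3$affinity - snf_oracle(mats3, K = 4, t = 3))), 1e-10)
})

test_that("fusing copies of one network preserves its affinity ranking", {
  # a similarity network with graded, locality-structured affinities
  # (patients on a latent 1-d manifold), the regime cross-diffusion is
  # built for; K ~ n/3 keeps the kernel genuinely local
  # 10 nodes leave too few pairs for a stable rank statistic, so several
  # seeds are pooled at n = 30 where the kernel resolves the locality
  rhos <- vapply(1:5, function(s) {
    A <- withr::with_seed(s, {
      x <- sort(runif(30))
      A <- exp(-as.matrix(dist(x)) / 0.1)
      diag(A) <- 0
      A
    })
    fused <- snf_fuse(list(A, A, A), K = 10, t = 5)
    ut <- upper.tri(A)
    cor(A[ut], fused$affinity[ut], method = "spearman")
  }, numeric(1))
  expect_true(all(rhos >= 0.9))
})

test_that("fused affinities are symmetric, nonnegative, and order-invariant", {
  A <- random_affinity(8, 82)
  B <- random_affinity(8, 83)
  f1 <- snf_fuse(list(A, B), K = 4, t = 5)
  expect_equal(f1$affinity, t(f1$affinity))
  expect_true(all(f1$affinity >= 0))
  expect_equal(unname(diag(f1$affinity)), rep(0, 8))
  f2 <- snf_fuse(list(B, A), K = 4, t = 5)
  expect_equal(f1$affinity, f2$affinity, tolerance = 1e-12)
  expect_error(snf_fuse(list(A, random_affinity(9, 84))), "shape")
})

test_that("cross-diffusion is permutation-equivariant", {
  A <- random_affinity(8, 85)
  B <- random_affinity(8, 86)
  perm <- withr::with_seed(6, sample(8))
  f <- snf_fuse(list(A, B), K = 3, t = 4)$affinity
  fp <- snf_fuse(list(A[perm, perm], B[perm, perm]), K = 3, t = 4)$affinity
  expect_equal(fp, f[perm, perm], tolerance = 1e-12)
})

test_that("fusion sharpens a two-cluster structure shared by both sources", {
  co <- generate_multiomics(synthetic_spec(50, dims = c(300, 300),
                                           n_informative = 60, effect_size = 2,
                                           imbalance = 0.6, seed = 55))
  psns <- suppressWarnings(lapply(co$matrices, build_psn))
  fused <- snf_fuse(psns, t = 10)
  y <- co$labels
  ut <- upper.tri(fused$affinity)
  same <- outer(y, y, "==") & ut
  diff <- outer(y, y, "!=") & ut
  expect_gt(mean(fused$affinity[same]), mean(fused$affinity[diff]))
  g <- as_psn(fused)
  expect_s3_class(g, "psn")
  expect_true(all(g$affinity <= 1))
})

test_that("feature-level fusion averages centralities and concatenates modules", {
  b1 <- generate_block_affinity(c(10, 10), seed = 91)
  b2 <- generate_block_affinity(c(10, 10), within = 0.8, seed = 92)
  t1 <- assemble_features(psn(b1$affinity), k_grid = 2:3, seed = 1)
  t2 <- assemble_features(psn(b2$affinity), k_grid = 2:4, seed = 1)
  fused <- fuse_feature_level(list(t1, t2), names = c("expr", "methyl"))
  p <- ncol(t1$values) - 13L
  q <- ncol(t2$values) - 13L
  expect_equal(ncol(fused$values), 13L + p + q)
  expect_equal(fused$values[, 1:13], (t1$values[, 1:13] + t2$values[, 1:13]) / 2)
  expect_true(all(grepl("^(expr|methyl):modularity:", fused$column_meta[-(1:13)])))

  # identical tables leave the centrality block unchanged; three tables average
  same <- fuse_feature_level(list(t1, t1))
  expect_equal(same$values[, 1:13], t1$values[, 1:13])
  three <- fuse_feature_level(list(t1, t1, t2))
  expect_equal(three$values[, 1:13],
               (2 * t1$values[, 1:13] + t2$values[, 1:13]) / 3)

  t2_perm <- t2
  t2_perm$values <- t2_perm$values[c(2:20, 1), ]
  expect_error(fuse_feature_level(list(t1, t2_perm)), "ordering")
})
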