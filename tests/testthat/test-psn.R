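toy_omics <- function(values, ids = NULL) {
  ids <- ids %||% sprintf("P%d", seq_len(nrow(values)))
  dimnames(values) <- list(ids, sprintf("f%d", seq_len(ncol(values))))
  omics_matrix(values)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("patient correlation reproduces hand-computed Pearson values", {
  om <- toy_omics(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(4, 3, 2, 1),
                        c(1, 3, 2, 4)))
  r <- patient_correlation(om)
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(unname(r[1, 2]), 1)    # perfect linear relation
  expect_equal(unname(r[1, 3]), -1)   # perfect anti-correlation
  expect_equal(unname(r[1, 4]), 0.8)  # direct evaluation of the closed form
  expect_equal(r, t(r))
})

test_that("zero-variance patient profiles are rejected by name", {
  om <- toy_omics(rbind(c(1, 1, 1), c(1, 2, 3)), ids = c("flat", "ok"))
  expect_error(patient_correlation(om), "flat")
})

test_that("soft threshold maps correlations to [0,1] via the signed transform", {
  r <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(unname(soft_threshold(r, 3)[1, 2]), 1)
  r[1, 2] <- r[2, 1] <- -1
  expect_equal(unname(soft_threshold(r, 7)[1, 2]), 0)
  r[1, 2] <- r[2, 1] <- 0
  expect_equal(unname(soft_threshold(r, 2)[1, 2]), 0.25)
  expect_error(soft_threshold(r, 0.5), "beta")
})

test_that("soft threshold is entrywise monotone decreasing in beta", {
  co <- generate_multiomics(synthetic_spec(20, dims = 50, n_informative = 10,
                                           effect_size = 1, imbalance = 0.6,
                                           seed = 3))
  r <- patient_correlation(co$matrices[[1]])
  a1 <- soft_threshold(r, 2)
  a2 <- soft_threshold(r, 5)
  expect_true(all(a1 - a2 >= -1e-12))
})

test_that("scale-free fit index is 0 for degenerate connectivity and high for PA graphs", {
  expect_equal(scale_free_fit_index(affinity_K4()), 0)      # all k equal
  # exactly two occupied bins: two distinct connectivity values
  W <- affinity_star(5)
  expect_equal(scale_free_fit_index(W), 0)
  g <- generate_pa_graph(500, 2, seed = 7)
  expect_gte(scale_free_fit_index(g), 0.8)
})

test_that("soft-threshold selection matches an exhaustive-scan oracle", {
  co <- generate_multiomics(synthetic_spec(60, dims = 300, n_informative = 60,
                                           effect_size = 2, imbalance = 0.6,
                                           seed = 21))
  r <- patient_correlation(co$matrices[[1]])
  target <- 0.8
  # independent brute force over the whole grid
  fits <- vapply(1:20, function(b) scale_free_fit_index(soft_threshold(r, b)),
                 numeric(1))
  qualifying <- which(fits >= target)
  expected_beta <- if (length(qualifying)) min(qualifying) else which.max(fits)
  sel <- suppressWarnings(select_soft_threshold(r, target_r2 = target))
  expect_equal(sel$beta, expected_beta)
  if (length(qualifying)) expect_gte(sel$fit_r2, target)
})

test_that("selection returns the smallest qualifying beta or the argmax fallback", {
  # a PA graph's own affinity qualifies immediately at beta = 1
  g <- generate_pa_graph(300, 2, seed = 5)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  corr_like <- 2 * W / max(W) - 1  # invert the signed transform at beta 1
  sel <- select_soft_threshold(corr_like, target_r2 = 0.8)
  expect_equal(sel$beta, 1L)
  # unreachable target: fall back to argmax with a warning
  expect_warning(sel2 <- select_soft_threshold(corr_like, target_r2 = 0.999),
                 "argmax")
  expect_equal(sel2$fit_r2, max(sel2$scan$fit_r2))
})

test_that("build_psn yields a valid affinity with recorded beta", {
  co <- generate_multiomics(synthetic_spec(30, dims = 100, n_informative = 20,
                                           effect_size = 2, imbalance = 0.6,
                                           seed = 9))
  g <- suppressWarnings(build_psn(co$matrices[[1]]))
  A <- g$affinity
  expect_equal(A, t(A))
  expect_equal(unname(diag(A)), rep(0, 30))
  expect_true(all(A >= 0 & A <= 1))
  expect_true(g$beta >= 1)
  expect_identical(patient_ids(g), patient_ids(co$matrices[[1]]))
})

test_that("duplicate patient profiles get maximal affinity", {
  vals <- withr::with_seed(2, matrix(rnorm(5 * 20), 5, 20))
  vals[2, ] <- vals[1, ]
  g <- suppressWarnings(build_psn(toy_omics(vals), beta_grid = 1:3))
  expect_equal(unname(g$affinity[1, 2]), 1)
})

test_that("two-cluster structure appears as higher within-cluster affinity", {
  co <- generate_multiomics(synthetic_spec(60, dims = 200, n_informative = 50,
                                           effect_size = 2, imbalance = 0.6,
                                           seed = 13))
  g <- suppressWarnings(build_psn(co$matrices[[1]]))
  y <- co$labels
  same <- outer(y, y, "==") & upper.tri(g$affinity)
  diff <- outer(y, y, "!=") & upper.tri(g$affinity)
  expect_gt(mean(g$affinity[same]), mean(g$affinity[diff]))
})

test_that("PSN construction is equivariant under patient permutation", {
  co <- generate_multiomics(synthetic_spec(25, dims = 80, n_informative = 15,
                                           effect_size = 1.5, imbalance = 0.6,
                                           seed = 17))
  om <- co$matrices[[1]]
  perm <- withr::with_seed(3, sample(25))
  omp <- omics_matrix(om$values[perm, ], omics_name = om$omics_name)
  g <- suppressWarnings(build_psn(om))
  gp <- suppressWarnings(build_psn(omp))
  expect_equal(gp$affinity, g$affinity[perm, perm])
  expect_equal(gp$beta, g$beta)
})

test_that("PSN TSV round trip preserves affinity and metadata", {
  co <- generate_multiomics(synthetic_spec(15, dims = 60, n_informative = 10,
                                           effect_size = 2, imbalance = 0.6,
                                           seed = 19))
  g <- suppressWarnings(build_psn(co$matrices[[1]]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psn(g, path)
  g2 <- read_psn(path)
  expect_equal(g2$affinity, g$affinity, tolerance = 1e-8)
  expect_equal(g2$beta, g$beta)
  expect_equal(g2$omics_name, g$omics_name)
})
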