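test_that("stratified folds preserve class counts, partition, and determinism", {
  y <- rep(c(0L, 1L), c(6, 3))
  folds <- stratified_folds(y, 3, seed = 1)
  for (f in folds) {
    expect_equal(sum(y[f$test_idx] == 0L), 2L)
    expect_equal(sum(y[f$test_idx] == 1L), 1L)
    expect_setequal(c(f$train_idx, f$test_idx), 1:9)
  }
  tests <- lapply(folds, `[[`, "test_idx")
  expect_setequal(unlist(tests), 1:9)
  expect_equal(sum(lengths(tests)), 9L)  # pairwise disjoint given the union
  expect_identical(stratified_folds(y, 3, seed = 1), folds)
  expect_false(identical(stratified_folds(y, 3, seed = 2), folds))
  expect_error(stratified_folds(y, 4, seed = 1), "class 1")
})

test_that("metrics match their closed forms on forced cases", {
  perfect <- compute_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0), c(0.1, 0.9, 0.8, 0.2))
  expect_equal(unlist(perfect), c(accuracy = 1, f1 = 1, auc = 1))
  y <- rep(c(0L, 1L), c(77, 23))
  lazy <- compute_metrics(y, rep(0L, 100), rep(0.3, 100))
  expect_equal(lazy$accuracy, 0.77)
  expect_equal(lazy$f1, 0)
  expect_equal(lazy$auc, 0.5)  # constant score: midrank AUC is exactly 1/2
  expect_true(is.na(compute_metrics(c(1, 1), c(1, 0), c(0.9, 0.1))$auc))
  expect_error(compute_metrics(c(0, 1), c(0, 1, 1)), "mismatch")
})

test_that("rank-statistic AUC agrees with pROC and is 0.5 on random scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    y <- rbinom(80, 1, 0.4)
    prob <- runif(80)
  })
  ours <- compute_metrics(y, as.integer(prob > 0.5), prob)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  withr::with_seed(32, {
    y2 <- rbinom(2000, 1, 0.5)
    p2 <- runif(2000)
  })
  expect_equal(compute_metrics(y2, as.integer(p2 > 0.5), p2)$auc, 0.5,
               tolerance = 0.05)
})

logreg_factory <- function(hyper) {
  function(X_train, y_train, X_test, seed) {
    keep <- seq_len(min(hyper$n_keep, ncol(X_train)))
    fit <- suppressWarnings(glm(y ~ ., family = binomial(),
                                data = data.frame(y = y_train, X_train[, keep, drop = FALSE])))
    prob <- predict(fit, newdata = data.frame(X_test[, keep, drop = FALSE]),
                    type = "response")
    list(labels = as.integer(prob > 0.5), prob = prob)
  }
}

cv_fixture <- function(n = 90, seed = 33) {
  withr::with_seed(seed, {
    y <- rep(0:1, length.out = n)
    X <- cbind(rnorm(n, 1.5 * y), matrix(rnorm(n * 3), n, 3))
    colnames(X) <- paste0("f", 1:4)
    list(X = X, y = y)
  })
}

test_that("nested CV selects from the grid without leakage", {
  d <- cv_fixture()
  rep_ <- nested_cv(d$X, d$y, logreg_factory,
                    hyper_grid = list(list(n_keep = 1), list(n_keep = 4)),
                    outer_k = 3, inner_k = 3, repeats = 2, seed = 7)
  expect_equal(nrow(rep_$folds), 6L)
  for (r in seq_along(rep_$assignments)) {
    outer <- rep_$assignments[[r]]
    expect_setequal(unlist(lapply(outer, `[[`, "test_idx")), seq_along(d$y))
    for (fo in seq_along(outer)) {
      inner <- rep_$inner_assignments[[r]][[fo]]
      for (fi in inner) {
        expect_length(intersect(fi$train_idx, outer[[fo]]$test_idx), 0L)
        expect_length(intersect(fi$test_idx, outer[[fo]]$test_idx), 0L)
        expect_true(all(c(fi$train_idx, fi$test_idx) %in% outer[[fo]]$train_idx))
      }
    }
  }
  # summary equals recomputation from the per-fold table
  expect_equal(unname(rep_$summary["accuracy", "mean"]), mean(rep_$folds$accuracy))
  expect_equal(unname(rep_$summary["f1", "sd"]), sd(rep_$folds$f1))
  expect_equal(unname(rep_$summary["auc", "mean"]),
               mean(rep_$folds$auc, na.rm = TRUE))
})

test_that("a singleton grid short-circuits the inner loop", {
  d <- cv_fixture(seed = 34)
  rep_ <- nested_cv(d$X, d$y, logreg_factory,
                    hyper_grid = list(list(n_keep = 2)),
                    outer_k = 3, repeats = 1, seed = 8)
  expect_true(all(rep_$folds$hyper_index == 1L))
  expect_true(all(vapply(rep_$chosen, function(h) h$n_keep == 2, logical(1))))
  expect_identical(rep_$inner_assignments[[1]][[1]], NULL)
})

test_that("nested CV is reproducible under the master seed", {
  d <- cv_fixture(seed = 35)
  r1 <- nested_cv(d$X, d$y, logreg_factory,
                  hyper_grid = list(list(n_keep = 1), list(n_keep = 3)),
                  repeats = 1, seed = 10)
  r2 <- nested_cv(d$X, d$y, logreg_factory,
                  hyper_grid = list(list(n_keep = 1), list(n_keep = 3)),
                  repeats = 1, seed = 10)
  expect_identical(r1$folds, r2$folds)
})

test_that("the MLP pipeline factory z-scores inside training folds", {
  d <- cv_fixture(n = 60, seed = 36)
  factory <- mlp_pipeline_factory(list(layer_sizes = c(4), max_epochs = 15,
                                       patience = 3, dropout = 0))
  runner <- factory(list())
  pred <- runner(d$X[1:40, ], d$y[1:40], d$X[41:60, ], seed = 1)
  expect_length(pred$labels, 20L)
  expect_true(all(pred$prob >= 0 & pred$prob <= 1))
})
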