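#' Stratified k-fold assignments
#'
#' Partitions samples into `k` disjoint, exhaustive folds preserving the
#' class proportions within one sample per class.
#'
#' @param labels Binary 0/1 labels.
#' @param k Number of folds, `>= 2`; every class must have at least `k`
#'   members.
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train_idx, test_idx)`.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  y <- as.integer(labels)
  if (k < 2) stop_param("k", "must be >= 2")
  for (cl in c(0L, 1L)) {
    if (sum(y == cl) < k) {
      stop(sprintf("class %d has fewer than k = %d members", cl, k))
    }
  }
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(y == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train_idx = which(fold_of != f), test_idx = which(fold_of == f))
  })
}

#' Binary classification metrics
#'
#' Accuracy, F1 with positive class 1 (the clinical event), and ROC-AUC
#' computed as the rank statistic (Mann-Whitney with midrank tie
#' correction). AUC is `NA` when only one class is present in the truth
#' (undefined, not 0.5); F1 is 0 when there are no true positives.
#'
#' @param y_true,y_pred Binary 0/1 vectors of equal length.
#' @param y_prob Class-1 probabilities (for AUC); optional.
#' @return List with `accuracy`, `f1`, `auc`.
#' @export
compute_metrics <- function(y_true, y_pred, y_prob = NULL) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  acc <- mean(y_true == y_pred)
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  auc <- NA_real_
  if (!is.null(y_prob)) {
    if (length(y_prob) != length(y_true)) stop("length mismatch")
    n1 <- sum(y_true == 1L)
    n0 <- sum(y_true == 0L)
    if (n1 > 0L && n0 > 0L) {
      r <- rank(y_prob)  # midranks handle ties
      auc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
    }
  }
  list(accuracy = acc, f1 = f1, auc = auc)
}

#' Nested cross-validation
#'
#' Two-level cross-validation for unbiased evaluation under
#' hyperparameter tuning: for each outer fold, an inner k-fold grid
#' search over `hyper_grid` on the outer-training data picks the
#' hyperparameter set with the best mean inner score; a model with that
#' set is then fit on the full outer-training fold and scored on the
#' untouched outer-test fold. The whole procedure is repeated over
#' `repeats` random fold assignments to populate the reported mean and
#' standard deviation. All data-dependent fitting (including z-scoring
#' statistics) must happen inside `pipeline_factory`'s fit on the
#' training data it is given.
#'
#' @param features Numeric matrix (samples by features).
#' @param labels Binary 0/1 labels.
#' @param pipeline_factory Function taking one hyperparameter list and
#'   returning `function(X_train, y_train, X_test, seed)` that fits on
#'   the training data and returns `list(labels, prob)` for `X_test`.
#' @param hyper_grid List of hyperparameter lists (nonempty). A grid of
#'   size 1 short-circuits the inner loop.
#' @param outer_k,inner_k Fold counts (default 3 and 3).
#' @param repeats Number of repeated random splits (default 3).
#' @param seed Master seed; repeat `r` uses `seed + r - 1` for its folds.
#' @param select_metric Inner-loop model-selection metric: `"f1"`,
#'   `"accuracy"`, or `"auto"` (F1 when the class split is more extreme
#'   than 60/40, accuracy otherwise).
#' @return An object of class `cv_report`: `folds` (data.frame with one
#'   row per repeat and outer fold: metrics and the chosen hyperparameter
#'   index), `summary` (mean and sd per metric), `chosen` (hyperparameter
#'   list per fold), `assignments` (outer folds per repeat),
#'   `inner_assignments` (inner folds in original sample indices, for
#'   leakage auditing), `repeat_seeds`.
#' @export
nested_cv <- function(features, labels, pipeline_factory, hyper_grid,
                      outer_k = 3, inner_k = 3, repeats = 3, seed = 1,
                      select_metric = c("auto", "f1", "accuracy")) {
  select_metric <- match.arg(select_metric)
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (length(hyper_grid) < 1L) stop_param("hyper_grid", "must be nonempty")
  if (select_metric == "auto") {
    select_metric <- if (max(mean(y), 1 - mean(y)) > 0.6) "f1" else "accuracy"
  }
  repeat_seeds <- seed + seq_len(repeats) - 1L
  rows <- list()
  chosen <- list()
  assignments <- list()
  inner_assignments <- list()
  for (r in seq_len(repeats)) {
    outer <- stratified_folds(y, outer_k, seed = repeat_seeds[r])
    assignments[[r]] <- outer
    inner_assignments[[r]] <- vector("list", length(outer))
    for (fo in seq_along(outer)) {
      tr <- outer[[fo]]$train_idx
      te <- outer[[fo]]$test_idx
      best_h <- 1L
      if (length(hyper_grid) > 1L) {
        inner <- stratified_folds(y[tr], inner_k,
                                  seed = repeat_seeds[r] * 131L + fo)
        # inner folds in original sample indices, for leakage auditing
        inner_assignments[[r]][[fo]] <- lapply(inner, function(f) {
          list(train_idx = tr[f$train_idx], test_idx = tr[f$test_idx])
        })
        inner_scores <- vapply(seq_along(hyper_grid), function(h) {
          runner <- pipeline_factory(hyper_grid[[h]])
          sc <- vapply(seq_along(inner), function(fi) {
            itr <- tr[inner[[fi]]$train_idx]
            ite <- tr[inner[[fi]]$test_idx]
            pred <- runner(X[itr, , drop = FALSE], y[itr],
                           X[ite, , drop = FALSE],
                           seed = repeat_seeds[r] + 1000L * h + fi)
            m <- compute_metrics(y[ite], pred$labels, pred$prob)
            m[[if (select_metric == "f1") "f1" else "accuracy"]]
          }, numeric(1))
          mean(sc)
        }, numeric(1))
        best_h <- which.max(inner_scores)
      }
      runner <- pipeline_factory(hyper_grid[[best_h]])
      pred <- runner(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE],
                     seed = repeat_seeds[r] * 7L + fo)
      m <- compute_metrics(y[te], pred$labels, pred$prob)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, outer_fold = fo, accuracy = m$accuracy, f1 = m$f1,
        auc = m$auc, hyper_index = best_h)
      chosen[[length(chosen) + 1L]] <- hyper_grid[[best_h]]
    }
  }
  folds_df <- do.call(rbind, rows)
  summarize <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = sd(v, na.rm = TRUE))
  structure(list(
    folds = folds_df,
    summary = rbind(accuracy = summarize(folds_df$accuracy),
                    f1 = summarize(folds_df$f1),
                    auc = summarize(folds_df$auc)),
    chosen = chosen, assignments = assignments,
    inner_assignments = inner_assignments,
    repeat_seeds = repeat_seeds, select_metric = select_metric),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d repeats x %d outer folds (selection by %s)>\n",
              length(x$repeat_seeds), max(x$folds$outer_fold), x$select_metric))
  s <- x$summary
  for (m in rownames(s)) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, s[m, "mean"], s[m, "sd"]))
  }
  invisible(x)
}

#' MLP pipeline factory for nested cross-validation
#'
#' Returns, for one hyperparameter list (fields of [train_mlp()]), a
#' runner that z-scores with training-fold statistics, trains the MLP,
#' and predicts the test fold.
#'
#' @param defaults Named list of [train_mlp()] arguments overridden by
#'   each hyperparameter list.
#' @return Function suitable as `pipeline_factory` in [nested_cv()].
#' @export
mlp_pipeline_factory <- function(defaults = list()) {
  function(hyper) {
    args <- utils::modifyList(defaults, hyper)
    function(X_train, y_train, X_test, seed) {
      Ztr <- zscore_features(X_train)
      Zte <- zscore_features(X_test, center = attr(Ztr, "center"),
                             scale = attr(Ztr, "scale"))
      model <- do.call(train_mlp,
                       c(list(features = Ztr, labels = y_train, seed = seed),
                         args))
      predict_mlp(model, Zte)
    }
  }
}

#' End-to-end multi-omics pipeline on held-out data
#'
#' Runs the full method: per-omics rank-test prefilter, PSN construction,
#' omics fusion at the network level (similarity network fusion of the
#' PSNs, features extracted from the fused network) or the feature level
#' (features per PSN, centrality means + modularity concatenation),
#' z-scoring, MLP training on a stratified training split, and evaluation
#' on the held-out split. Network feature extraction sees all patients
#' (the network is transductive); labels of held-out patients are never
#' used for filtering, scaling, or training.
#'
#' @param matrices List of [omics_matrix] objects with identical patient
#'   ordering.
#' @param labels Binary 0/1 labels aligned to the patients.
#' @param fusion `"network"` or `"feature"`.
#' @param alpha Prefilter significance level (`NULL` skips the prefilter).
#' @param test_frac Held-out stratified fraction (default 0.3).
#' @param k_grid Module-count grid for feature extraction (`NULL` =
#'   default geometric grid).
#' @param snf_K,snf_t SNF neighborhood size and iteration count.
#' @param mlp_args Named list of [train_mlp()] overrides.
#' @param seed Integer seed controlling every stochastic step.
#' @return List with `metrics` (held-out accuracy/F1/AUC), `features`
#'   (the fused [network_features]), `model`, `split`, `psns`, and
#'   (network fusion) `fused`.
#' @export
run_pipeline <- function(matrices, labels, fusion = c("network", "feature"),
                         alpha = 0.001, test_frac = 0.3, k_grid = NULL,
                         snf_K = NULL, snf_t = 20, mlp_args = list(),
                         seed = 1) {
  fusion <- match.arg(fusion)
  labels <- align_labels(labels, patient_ids(matrices[[1L]]))

  test_idx <- with_seed(seed, unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1L, round(test_frac * length(idx))))
  })))
  train_idx <- setdiff(seq_along(labels), test_idx)

  # prefilter fitted on training labels only
  filtered <- lapply(matrices, function(om) {
    if (is.null(alpha)) return(om)
    tr_om <- omics_matrix(om$values[train_idx, , drop = FALSE],
                          omics_name = om$omics_name)
    keep <- attr(filter_features_ranktest(tr_om, labels[train_idx],
                                          alpha = alpha), "kept")
    omics_matrix(om$values[, keep, drop = FALSE], omics_name = om$omics_name)
  })

  psns <- lapply(filtered, build_psn)
  if (fusion == "network") {
    fused <- snf_fuse(psns, K = snf_K, t = snf_t)
    feats <- assemble_features(as_psn(fused), k_grid = k_grid, seed = seed)
  } else {
    fused <- NULL
    tables <- lapply(psns, assemble_features, k_grid = k_grid, seed = seed)
    feats <- fuse_feature_level(tables,
                                names = vapply(psns, `[[`, character(1),
                                               "omics_name"))
  }

  Xtr <- zscore_features(feats$values[train_idx, , drop = FALSE])
  Xte <- zscore_features(feats$values[test_idx, , drop = FALSE],
                         center = attr(Xtr, "center"),
                         scale = attr(Xtr, "scale"))
  model <- do.call(train_mlp, c(list(features = Xtr, labels = labels[train_idx],
                                     seed = seed), mlp_args))
  pred <- predict_mlp(model, Xte)
  metrics <- compute_metrics(labels[test_idx], pred$labels, pred$prob)
  list(metrics = metrics, features = feats, model = model,
       split = list(train_idx = train_idx, test_idx = test_idx),
       psns = psns, fused = fused)
}
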