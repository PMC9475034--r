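#' Integrated Gradients attribution for an MLP
#'
#' Path-integral attribution: for each sample the gradient of the model's
#' predicted-class logit is averaged along the straight line from a
#' baseline to the input (midpoint Riemann rule with `steps` points), and
#' scaled by the input-baseline difference. Differentiating the logit
#' rather than the softmax probability avoids gradient saturation. With
#' the default zero baseline on z-scored features, attributions measure
#' the contribution of each feature's deviation from the cohort mean.
#'
#' @param model An `mlp_model` (see [train_mlp()]).
#' @param x Numeric matrix (samples by features) or a single feature
#'   vector.
#' @param baseline Reference input `x'`: a single vector recycled across
#'   samples, or a matrix; defaults to the zero vector.
#' @param steps Riemann step count (default 300).
#' @param target Optional per-sample class index (0/1) to attribute;
#'   defaults to the model's predicted class at `x`.
#' @return An object of class `attribution_result` with `attributions`
#'   (samples by features), `baseline`, `steps`, `target`, and `saliency`
#'   (per-feature scores, see [saliency_scores()]).
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 300,
                                 target = NULL) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  p <- ncol(X)
  if (is.null(baseline)) baseline <- rep(0, p)
  B <- if (is.matrix(baseline)) baseline else
    matrix(baseline, nrow(X), p, byrow = TRUE)
  if (ncol(B) != p || nrow(B) != nrow(X)) {
    stop("baseline width does not match input width")
  }
  if (steps < 1) stop_param("steps", "must be >= 1")
  if (is.null(target)) target <- predict_mlp(model, X)$labels
  diff <- X - B
  grad_sum <- matrix(0, nrow(X), p)
  for (j in seq_len(steps)) {
    alpha <- (j - 0.5) / steps
    grad_sum <- grad_sum + mlp_input_gradient(model, B + alpha * diff, target)
  }
  attr_mat <- diff * grad_sum / steps
  dimnames(attr_mat) <- dimnames(X)
  structure(list(attributions = attr_mat, baseline = B[1L, ],
                 steps = as.integer(steps), target = target,
                 saliency = saliency_scores(attr_mat)),
            class = "attribution_result")
}

#' Per-feature saliency from an attribution matrix
#'
#' The magnitude (Euclidean norm) of each feature's attribution column
#' across all samples: features that consistently receive large
#' attributions, of either sign, score high.
#'
#' @param attributions Samples-by-features attribution matrix (or an
#'   `attribution_result`).
#' @return Nonnegative numeric vector, one score per feature.
#' @export
saliency_scores <- function(attributions) {
  A <- if (inherits(attributions, "attribution_result"))
    attributions$attributions else as.matrix(attributions)
  sqrt(colSums(A^2))
}

#' Recursive feature abridgement by attribution rank
#'
#' Trains the classifier on all features, computes Integrated-Gradients
#' saliency once, and then removes the least-salient features one at a
#' time (ranks frozen), retraining with fixed hyperparameters after each
#' removal and recording held-out metrics. Returns the full trace and the
#' feature subset maximizing the primary metric (ties favor fewer
#' features).
#'
#' @param features Z-scored numeric matrix (samples by features).
#' @param labels Binary 0/1 labels.
#' @param trainer Function `(X, y, seed) -> mlp_model`; defaults to
#'   [train_mlp()] with its default configuration.
#' @param test_frac Stratified held-out fraction used for the recorded
#'   metrics (default 0.3).
#' @param steps Riemann steps for the saliency computation.
#' @param metric Primary metric for picking the best subset (`"f1"` or
#'   `"accuracy"`).
#' @param seed Integer seed (split and all retrainings).
#' @return List with `trace` (data.frame: retained count, accuracy, F1,
#'   AUC per abridgement step, one row per retained count from
#'   `n_features` down to 1), `best_subset` (column indices), `best_metrics`,
#'   `full_metrics`, and `saliency_order` (feature indices, least salient
#'   first).
#' @export
recursive_abridgement <- function(features, labels, trainer = NULL,
                                  test_frac = 0.3, steps = 50,
                                  metric = c("f1", "accuracy"), seed = 1) {
  metric <- match.arg(metric)
  X <- as.matrix(features)
  y <- as.integer(labels)
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 features to abridge")
  trainer <- trainer %||% function(X, y, seed) train_mlp(X, y, seed = seed)

  test_idx <- with_seed(seed, unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(test_frac * length(idx))))
  })))
  tr <- setdiff(seq_len(nrow(X)), test_idx)

  eval_subset <- function(cols, seed_off) {
    model <- trainer(X[tr, cols, drop = FALSE], y[tr], seed + seed_off)
    pred <- predict_mlp(model, X[test_idx, cols, drop = FALSE])
    list(model = model,
         metrics = compute_metrics(y[test_idx], pred$labels, pred$prob))
  }

  full <- eval_subset(seq_len(p), 0L)
  ig <- integrated_gradients(full$model, X[tr, , drop = FALSE], steps = steps)
  order_asc <- order(ig$saliency)  # least salient first; ranks frozen

  trace <- vector("list", p)
  trace[[1L]] <- c(retained = p, full$metrics)
  subsets <- vector("list", p)
  subsets[[1L]] <- seq_len(p)
  for (d in seq_len(p - 1L)) {
    keep <- sort(setdiff(seq_len(p), order_asc[seq_len(d)]))
    res <- eval_subset(keep, d)
    trace[[d + 1L]] <- c(retained = p - d, res$metrics)
    subsets[[d + 1L]] <- keep
  }
  trace_df <- do.call(rbind, lapply(trace, function(r) {
    data.frame(retained = r$retained, accuracy = r$accuracy, f1 = r$f1,
               auc = r$auc)
  }))
  scores <- trace_df[[metric]]
  scores[is.na(scores)] <- -Inf
  best_i <- which(scores == max(scores))
  best_i <- best_i[which.min(trace_df$retained[best_i])]  # ties -> fewer features
  list(trace = trace_df,
       best_subset = subsets[[best_i]],
       best_metrics = trace[[best_i]][c("accuracy", "f1", "auc")],
       full_metrics = full$metrics,
       saliency_order = order_asc)
}
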