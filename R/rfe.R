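# Fit one RFE estimator and return per-feature importances
# (|coefficient| for linear estimators, impurity importance for trees)
# plus training accuracy.
rfe_fit_rank <- function(X, y, estimator, seed) {
  yf <- factor(y, levels = c(0L, 1L))
  p <- ncol(X)
  imp <- rep(0, p)
  acc <- NA_real_
  if (estimator == "svm_linear") {
    fit <- e1071::svm(X, yf, kernel = "linear", scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)
    imp <- abs(as.numeric(w))
    acc <- mean(predict(fit, X) == yf)
  } else if (estimator == "logistic") {
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    cf <- coef(fit)[-1L]
    cf[is.na(cf)] <- 0
    imp <- abs(as.numeric(cf))
    acc <- mean((predict(fit, type = "response") > 0.5) == (y == 1L))
  } else if (estimator == "decision_tree") {
    df <- data.frame(y = yf, X)
    fit <- rpart::rpart(y ~ ., data = df, method = "class")
    vi <- fit$variable.importance
    if (!is.null(vi)) {
      pos <- match(names(vi), colnames(X))
      imp[pos[!is.na(pos)]] <- vi[!is.na(pos)]
    }
    acc <- mean(predict(fit, type = "class") == yf)
  } else if (estimator == "random_forest") {
    fit <- with_seed(seed, randomForest::randomForest(X, yf, ntree = 200))
    imp <- as.numeric(randomForest::importance(fit)[, 1L])
    acc <- mean(predict(fit, X) == yf)
  } else {
    stop_param("estimator", "must be one of svm_linear, logistic, decision_tree, random_forest")
  }
  list(importance = imp, accuracy = acc)
}

#' Recursive feature elimination
#'
#' Wrapper feature selection: iteratively fits the estimator on the
#' surviving features, ranks features by the estimator's criterion
#' (absolute coefficient for linear estimators, impurity importance for
#' trees), removes exactly the single lowest-ranked feature, and repeats
#' until `n_select` features remain. Runs `n_features - n_select`
#' iterations.
#'
#' @param features Numeric matrix (samples by features); z-scored input
#'   recommended for the linear estimators.
#' @param labels Binary 0/1 labels.
#' @param estimator One of `"svm_linear"`, `"logistic"`,
#'   `"decision_tree"`, `"random_forest"`.
#' @param n_select Number of features to retain.
#' @param seed Integer seed (used by stochastic estimators).
#' @return An object of class `rfe_result`:
#'   \describe{
#'     \item{ranking}{all feature indices as a permutation, ordered from
#'       first eliminated (least important) to most important; the final
#'       survivors appear last, ordered by their final-fit importance.}
#'     \item{selected}{sorted indices of the `n_select` retained features.}
#'     \item{trace}{data.frame of per-iteration feature count, removed
#'       index, and estimator training accuracy.}
#'   }
#' @export
rfe_select <- function(features, labels,
                       estimator = c("svm_linear", "logistic",
                                     "decision_tree", "random_forest"),
                       n_select, seed = 1) {
  estimator <- match.arg(estimator)
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  y <- as.integer(labels)
  p <- ncol(X)
  if (n_select < 1 || n_select > p) {
    stop_param("n_select", "must satisfy 1 <= n_select <= n_features")
  }
  surviving <- seq_len(p)
  eliminated <- integer(0)
  trace <- list()
  it <- 0L
  while (length(surviving) > n_select) {
    it <- it + 1L
    fit <- tryCatch(
      rfe_fit_rank(X[, surviving, drop = FALSE], y, estimator, seed + it),
      error = function(e) stop(sprintf("estimator fit failed at iteration %d: %s",
                                       it, conditionMessage(e)), call. = FALSE))
    drop_local <- which.min(fit$importance)  # ties -> lowest index
    removed <- surviving[drop_local]
    eliminated <- c(eliminated, removed)
    trace[[it]] <- data.frame(iteration = it,
                              n_features = length(surviving),
                              removed = removed,
                              train_accuracy = fit$accuracy)
    surviving <- surviving[-drop_local]
  }
  # order survivors by final-fit importance (least important first)
  if (length(surviving) > 1L) {
    fit <- rfe_fit_rank(X[, surviving, drop = FALSE], y, estimator, seed)
    surv_order <- surviving[order(fit$importance)]
  } else {
    surv_order <- surviving
  }
  structure(list(ranking = c(eliminated, surv_order),
                 selected = sort(surviving),
                 trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(iteration = integer(0), n_features = integer(0),
                              removed = integer(0), train_accuracy = numeric(0)),
                 estimator = estimator, n_select = as.integer(n_select)),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result: %s estimator, %d feature(s) selected of %d, %d iterations>\n",
              x$estimator, length(x$selected), length(x$ranking), nrow(x$trace)))
  invisible(x)
}
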