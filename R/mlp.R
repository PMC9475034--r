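#' Class weights for imbalanced binary outcomes
#'
#' `weight_i = max(n_0, n_1) / n_i`: the majority class gets weight 1 and
#' the minority class is up-weighted by the imbalance ratio, so both
#' classes contribute equal total mass to the training loss.
#'
#' @param labels Binary 0/1 labels.
#' @return Numeric vector `c(weight_0, weight_1)`.
#' @export
compute_class_weights <- function(labels) {
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  c(max(n0, n1) / n0, max(n0, n1) / n1)
}

#' Class-weighted cross-entropy loss
#'
#' Mean over samples of `-weight[y] * log p(y)`, with the true-class
#' probability clipped at `1e-12`. With unit weights this is the standard
#' cross-entropy.
#'
#' @param probabilities Row-normalized n-by-2 matrix of class
#'   probabilities (columns = classes 0 and 1).
#' @param labels Binary 0/1 labels.
#' @param class_weights `c(weight_0, weight_1)`; default unit weights.
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probabilities, labels, class_weights = c(1, 1)) {
  probabilities <- as.matrix(probabilities)
  stopifnot(ncol(probabilities) == 2L, nrow(probabilities) == length(labels))
  idx <- cbind(seq_along(labels), as.integer(labels) + 1L)
  p <- pmax(probabilities[idx], 1e-12)
  w <- class_weights[as.integer(labels) + 1L]
  mean(-w * log(p))
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. Returns logits plus cached pre-activations / activations
# for backprop. `masks` supplies inverted-dropout masks (NULL = inference).
mlp_forward <- function(model, X, masks = NULL) {
  L <- length(model$W)
  H <- vector("list", L + 1L)
  Z <- vector("list", L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- H[[l]] %*% model$W[[l]] + matrix(model$b[[l]], nrow(X),
                                               length(model$b[[l]]), byrow = TRUE)
    if (l < L) {
      A <- relu(Z[[l]])
      if (!is.null(masks)) A <- A * masks[[l]]
      H[[l + 1L]] <- A
    } else {
      H[[l + 1L]] <- Z[[l]]
    }
  }
  list(logits = H[[L + 1L]], H = H, Z = Z)
}

# Backward pass from a gradient on the logits; returns per-layer weight /
# bias gradients (and the input gradient).
mlp_backward <- function(model, fwd, d_logits, masks = NULL) {
  L <- length(model$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- d_logits
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(fwd$H[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(model$W[[l]])
      if (!is.null(masks)) delta <- delta * masks[[l - 1L]]
      delta <- delta * (fwd$Z[[l - 1L]] > 0)
    } else {
      delta <- delta %*% t(model$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = delta)
}

init_mlp_params <- function(input_dim, layer_sizes) {
  sizes <- c(input_dim, layer_sizes, 2L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L], sd = sqrt(2 / fan_in)),
                     fan_in, sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

#' Train a feed-forward neural network classifier
#'
#' A small multilayer perceptron for binary outcomes: ReLU hidden layers
#' with inverted dropout, a 2-unit softmax output, class-weighted
#' cross-entropy loss minimized by Adam, and early stopping on a 10%
#' stratified validation split of the training data. When the class split
#' is more extreme than 60/40 the loss is weighted per
#' [compute_class_weights()]; otherwise unit weights are used. Training
#' is fully reproducible under `seed`.
#'
#' @param features Z-scored numeric matrix (samples by features).
#' @param labels Binary 0/1 labels, at least 2 samples per class.
#' @param layer_sizes Hidden layer widths (default `c(8, 64, 4, 8)`).
#' @param lr Adam learning rate (default 0.01).
#' @param batch_size Minibatch size (default 8).
#' @param dropout Hidden-layer dropout rate (default 0.5).
#' @param max_epochs Maximum epochs (default 200).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 20); `patience = 0` stops at the first
#'   non-improving epoch.
#' @param val_frac Validation fraction for early stopping (default 0.1).
#' @param class_weights Optional `c(w0, w1)` override of the imbalance
#'   rule.
#' @param seed Integer seed (initialization, split, shuffling, dropout).
#' @return An object of class `mlp_model` with layer weights/biases, the
#'   configuration, `class_weights`, and a per-epoch `training_log`.
#' @export
train_mlp <- function(features, labels, layer_sizes = c(8, 64, 4, 8),
                      lr = 0.01, batch_size = 8, dropout = 0.5,
                      max_epochs = 200, patience = 20, val_frac = 0.1,
                      class_weights = NULL, seed = 1) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  stopifnot(nrow(X) == length(y))
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L) {
    stop("need at least 2 samples per class")
  }
  if (is.null(class_weights)) {
    prop <- max(mean(y), 1 - mean(y))
    class_weights <- if (prop > 0.6) compute_class_weights(y) else c(1, 1)
  }

  with_seed(seed, {
    # stratified validation split for early stopping
    val_idx <- unlist(lapply(c(0L, 1L), function(cl) {
      idx <- which(y == cl)
      n_val <- max(1L, round(val_frac * length(idx)))
      sample(idx, n_val)
    }))
    tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

    model <- init_mlp_params(ncol(X), layer_sizes)
    model$layer_sizes <- layer_sizes
    adam_m <- lapply(c(model$W, model$b), function(p) p * 0)
    adam_v <- adam_m
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L

    n_hidden <- length(layer_sizes)
    best_val <- Inf
    best <- model[c("W", "b")]
    wait <- 0L
    log_rows <- vector("list", max_epochs)

    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(nrow(Xtr))
      starts <- seq(1L, length(perm), by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- perm[s:min(s + batch_size - 1L, length(perm))]
        Xb <- Xtr[bi, , drop = FALSE]; yb <- ytr[bi]
        masks <- NULL
        if (dropout > 0) {
          masks <- lapply(layer_sizes, function(h) {
            matrix((runif(length(bi) * h) >= dropout) / (1 - dropout),
                   length(bi), h)
          })
        }
        fwd <- mlp_forward(model, Xb, masks)
        probs <- softmax_rows(fwd$logits)
        onehot <- matrix(0, length(bi), 2L)
        onehot[cbind(seq_along(yb), yb + 1L)] <- 1
        w <- class_weights[yb + 1L]
        d_logits <- (probs - onehot) * w / length(bi)
        grads <- mlp_backward(model, fwd, d_logits, masks)
        loss_b <- weighted_cross_entropy(probs, yb, class_weights)
        if (!is.finite(loss_b)) {
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        }
        ep_loss <- ep_loss + loss_b * length(bi)

        # Adam update over the flattened parameter list
        step <- step + 1L
        params <- c(model$W, model$b)
        glist <- c(grads$dW, grads$db)
        for (j in seq_along(params)) {
          adam_m[[j]] <- b1 * adam_m[[j]] + (1 - b1) * glist[[j]]
          adam_v[[j]] <- b2 * adam_v[[j]] + (1 - b2) * glist[[j]]^2
          mhat <- adam_m[[j]] / (1 - b1^step)
          vhat <- adam_v[[j]] / (1 - b2^step)
          params[[j]] <- params[[j]] - lr * mhat / (sqrt(vhat) + eps)
        }
        model$W <- params[seq_len(n_hidden + 1L)]
        model$b <- params[(n_hidden + 2L):length(params)]
      }
      val_probs <- softmax_rows(mlp_forward(model, Xval)$logits)
      val_loss <- weighted_cross_entropy(val_probs, yval, class_weights)
      log_rows[[epoch]] <- data.frame(epoch = epoch,
                                      train_loss = ep_loss / nrow(Xtr),
                                      val_loss = val_loss)
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best <- model[c("W", "b")]
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > patience) break
      }
    }
    model$W <- best$W
    model$b <- best$b
    model$dropout_rate <- dropout
    model$class_weights <- class_weights
    model$activation <- "relu"
    model$config <- list(lr = lr, batch_size = batch_size,
                         max_epochs = max_epochs, patience = patience,
                         val_frac = val_frac, seed = seed)
    model$training_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
    class(model) <- "mlp_model"
    model
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model: %d-%s-2, dropout %.2f, class weights (%.2f, %.2f), %d epochs>\n",
              nrow(x$W[[1L]]), paste(x$layer_sizes, collapse = "-"),
              x$dropout_rate, x$class_weights[1L], x$class_weights[2L],
              max(x$training_log$epoch)))
  invisible(x)
}

#' Predict with a trained MLP
#'
#' Softmax over the output logits (dropout disabled); the predicted label
#' is the argmax, with ties resolved to class 0.
#'
#' @param model An `mlp_model`.
#' @param features Numeric matrix with the model's input width.
#' @return List with `labels` (0/1) and `prob` (class-1 probability).
#' @export
predict_mlp <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != nrow(model$W[[1L]])) {
    stop(sprintf("feature width %d does not match model input %d",
                 ncol(X), nrow(model$W[[1L]])))
  }
  probs <- softmax_rows(mlp_forward(model, X)$logits)
  list(labels = as.integer(probs[, 2L] > probs[, 1L]), prob = probs[, 2L])
}

# Gradient of a chosen output logit wrt each input feature, per sample.
# `target` is a per-sample class index (0/1); used by integrated gradients.
mlp_input_gradient <- function(model, X, target) {
  X <- as.matrix(X)
  fwd <- mlp_forward(model, X)
  d_logits <- matrix(0, nrow(X), 2L)
  d_logits[cbind(seq_len(nrow(X)), target + 1L)] <- 1
  mlp_backward(model, fwd, d_logits)$dX
}
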