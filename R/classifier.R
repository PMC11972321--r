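#' Dense classifier architecture specification
#'
#' The binary cardiovascular-risk classifier: fully connected layers of 128,
#' 64 and 32 ReLU units, each optionally followed by batch normalization,
#' and a single sigmoid output unit. Its flattened weight vector is the
#' search point the PCSO optimizer moves through.
#'
#' @param input_dim Number of input features.
#' @param hidden Hidden layer sizes (default `c(128, 64, 32)`).
#' @param batch_norm Standardize each hidden pre-activation to the training
#'   batch moments (non-affine; default `TRUE`).
#' @param dropout_rate Dropout probability in `[0, 1)`, active only during
#'   gradient refinement (default 0.1).
#' @param class_weight Positive-class weight of the loss (default 1).
#' @return A `network_spec`.
#' @export
network_spec <- function(input_dim, hidden = c(128L, 64L, 32L),
                         batch_norm = TRUE, dropout_rate = 0.1,
                         class_weight = 1) {
  stopifnot(input_dim >= 1L, all(hidden >= 1L),
            dropout_rate >= 0, dropout_rate < 1, class_weight > 0)
  sizes <- c(as.integer(input_dim), as.integer(hidden), 1L)
  layout <- list(); offset <- 0L
  for (l in seq_len(length(sizes) - 1L)) {
    nw <- sizes[l] * sizes[l + 1L]
    layout[[l]] <- list(layer = l, n_in = sizes[l], n_out = sizes[l + 1L],
                        w_from = offset + 1L, w_to = offset + nw,
                        b_from = offset + nw + 1L,
                        b_to = offset + nw + sizes[l + 1L])
    offset <- offset + nw + sizes[l + 1L]
  }
  structure(list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
                 sizes = sizes, batch_norm = isTRUE(batch_norm),
                 dropout_rate = dropout_rate, class_weight = class_weight,
                 layout = layout, n_params = offset),
            class = "network_spec")
}

#' Number of trainable parameters
#' @param spec A [network_spec()].
#' @return Integer parameter count.
#' @export
n_params <- function(spec) spec$n_params

#' Unflatten a weight vector into per-layer matrices
#'
#' @param weights Numeric vector of length `n_params(spec)`.
#' @param spec A [network_spec()].
#' @return List of `list(W, b)` per layer.
#' @export
unflatten_weights <- function(weights, spec) {
  if (length(weights) != spec$n_params)
    stop("weight vector has length ", length(weights), ", expected ",
         spec$n_params)
  lapply(spec$layout, function(s)
    list(W = matrix(weights[s$w_from:s$w_to], s$n_in, s$n_out),
         b = weights[s$b_from:s$b_to]))
}

#' Flatten per-layer matrices into a weight vector
#'
#' Exact inverse of [unflatten_weights()].
#'
#' @param layers List of `list(W, b)`.
#' @return Numeric vector.
#' @export
flatten_weights <- function(layers) {
  unlist(lapply(layers, function(l) c(as.numeric(l$W), l$b)),
         use.names = FALSE)
}

relu <- function(x) (x > 0) * x
sigmoid <- function(x) 1 / (1 + exp(-x))
BN_EPS <- 1e-5

# fast column-broadcast helpers (avoid sweep's aperm overhead)
row_shift <- function(M, v) M + rep(v, each = nrow(M))
row_scale <- function(M, v) M * rep(v, each = nrow(M))

#' Compute batch-normalization moments on a reference set
#'
#' For a given weight vector, runs the network over `X` and records the
#' per-unit mean and variance of every hidden pre-activation. Fixing these
#' training-set moments makes inference (and hence the PCSO fitness) a
#' deterministic function of the weight vector.
#'
#' @param spec A [network_spec()].
#' @param weights Flat weight vector.
#' @param X Reference feature matrix (typically the training split).
#' @return List of per-hidden-layer `list(mean, var)`.
#' @export
compute_bn_stats <- function(spec, weights, X) {
  layers <- unflatten_weights(weights, spec)
  a <- X
  stats_out <- vector("list", length(spec$hidden))
  for (l in seq_along(spec$hidden)) {
    # the additive bias cancels under batch normalization, so it is skipped
    z <- a %*% layers[[l]]$W
    mu <- colMeans(z)
    v <- colMeans(z * z) - mu^2
    v[v < 0] <- 0
    stats_out[[l]] <- list(mean = mu, var = v)
    zn <- row_scale(row_shift(z, -mu), 1 / sqrt(v + BN_EPS))
    a <- relu(zn)
  }
  stats_out
}

#' Forward pass of the dense classifier
#'
#' Deterministic inference: dropout is off and batch normalization uses the
#' supplied moments (when `bn_stats` is `NULL` and the spec uses batch norm,
#' moments are computed from `X` itself).
#'
#' @param spec A [network_spec()].
#' @param weights Flat weight vector.
#' @param X Feature matrix with `input_dim` columns.
#' @param bn_stats Optional output of [compute_bn_stats()].
#' @return Vector of probabilities in (0, 1).
#' @export
forward <- function(spec, weights, X, bn_stats = NULL) {
  if (!is.matrix(X)) X <- matrix(X, ncol = spec$input_dim)
  if (ncol(X) != spec$input_dim)
    stop("X has ", ncol(X), " columns, expected ", spec$input_dim)
  layers <- unflatten_weights(weights, spec)
  if (spec$batch_norm && is.null(bn_stats))
    bn_stats <- compute_bn_stats(spec, weights, X)
  a <- X
  for (l in seq_along(spec$hidden)) {
    if (spec$batch_norm) {
      st <- bn_stats[[l]]
      z <- row_scale(row_shift(a %*% layers[[l]]$W, -st$mean),
                     1 / sqrt(st$var + BN_EPS))
    } else {
      z <- row_shift(a %*% layers[[l]]$W, layers[[l]]$b)
    }
    a <- relu(z)
  }
  lout <- layers[[length(layers)]]
  as.numeric(sigmoid(row_shift(a %*% lout$W, lout$b)))
}

#' Class-weighted binary cross-entropy
#'
#' `mean(-(w * y * log p + (1 - y) * log(1 - p)))` with probabilities
#' clipped to `[eps, 1 - eps]`.
#'
#' @param probabilities Predicted probabilities.
#' @param y Binary 0/1 labels of the same length.
#' @param class_weight Positive-class weight `w`.
#' @param eps Clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
weighted_bce <- function(probabilities, y, class_weight = 1, eps = 1e-7) {
  if (length(probabilities) != length(y)) stop("length mismatch")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  mean(-(class_weight * y * log(p) + (1 - y) * log(1 - p)))
}

#' PCSO fitness of a weight vector
#'
#' The minimization target handed to the optimizer: the class-weighted BCE
#' on the validation split, with batch-norm moments fixed to the training
#' split so the value is deterministic per weight vector.
#'
#' @param weights Flat weight vector.
#' @param spec A [network_spec()].
#' @param train,val Disjoint lists with elements `X` and `y`.
#' @return Scalar validation loss.
#' @export
fitness_from_weights <- function(weights, spec, train, val) {
  if (!length(val$y)) stop("empty validation set")
  bn <- if (spec$batch_norm) compute_bn_stats(spec, weights, train$X) else NULL
  p <- forward(spec, weights, val$X, bn)
  weighted_bce(p, val$y, spec$class_weight)
}

#' Train the dense classifier with PCSO
#'
#' Splits the data into an internal train/validation pair, then runs
#' Predator Crow Search Optimization over the flattened weight vector inside
#' the symmetric box `[-weight_bound, weight_bound]`, minimizing the
#' validation weighted BCE. Optionally refines the best weights with a few
#' epochs of Adam gradient descent (off by default).
#'
#' @param spec A [network_spec()].
#' @param X Feature matrix (already preprocessed / z-scored).
#' @param y Binary 0/1 labels.
#' @param pop_size,max_iters PCSO population and iteration budget.
#' @param weight_bound Half-width of the weight search box (default 3).
#' @param val_fraction Fraction held out as the fitness validation split.
#' @param seed Integer seed (drives the split and the optimizer).
#' @param refine_epochs Adam refinement epochs (0 = off, the default).
#' @param learning_rate,batch_size Refinement hyperparameters (defaults
#'   0.001 and 32).
#' @param ... Further arguments to [pcso_config()].
#' @return A `pcso_classifier`: `spec`, `weights`, `bn_stats` (moments on
#'   the full data), `result` (the [pcso_optimize()] trace), `seed`.
#' @export
train_with_pcso <- function(spec, X, y, pop_size = 30L, max_iters = 150L,
                            weight_bound = 3, val_fraction = 0.2, seed = 1L,
                            refine_epochs = 0L, learning_rate = 1e-3,
                            batch_size = 32L, ...) {
  stopifnot(ncol(X) == spec$input_dim, length(y) == nrow(X))
  split <- stratified_split(y, fraction = 1 - val_fraction, seed = seed)
  train <- list(X = X[split$train, , drop = FALSE], y = y[split$train])
  val <- list(X = X[split$test, , drop = FALSE], y = y[split$test])
  cfg <- pcso_config(dim = spec$n_params, lower = -weight_bound,
                     upper = weight_bound, pop_size = pop_size,
                     max_iters = max_iters, seed = seed, ...)
  objective <- function(w) fitness_from_weights(w, spec, train, val)
  result <- pcso_optimize(objective, cfg)
  weights <- result$best_position
  refine_history <- NULL
  if (refine_epochs > 0L) {
    ref <- refine_with_adam(spec, weights, train$X, train$y,
                            epochs = refine_epochs, lr = learning_rate,
                            batch_size = batch_size, seed = seed)
    if (fitness_from_weights(ref$weights, spec, train, val) <
        result$best_fitness)
      weights <- ref$weights
    refine_history <- ref$history
  }
  bn <- if (spec$batch_norm) compute_bn_stats(spec, weights, X) else NULL
  structure(list(spec = spec, weights = weights, bn_stats = bn,
                 result = result, refine_history = refine_history,
                 seed = as.integer(seed)),
            class = "pcso_classifier")
}

#' Predict probabilities or labels from a fitted classifier
#'
#' @param object A `pcso_classifier`.
#' @param newdata Feature matrix.
#' @param type `"prob"` (default) or `"class"` (threshold 0.5).
#' @param ... Unused.
#' @return Probabilities or 0/1 labels.
#' @export
predict.pcso_classifier <- function(object, newdata, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  p <- forward(object$spec, object$weights, newdata, object$bn_stats)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
print.pcso_classifier <- function(x, ...) {
  cat(sprintf("pcso_classifier: %d-%s-1 network, %d weights, final fitness %.4f\n",
              x$spec$input_dim, paste(x$spec$hidden, collapse = "-"),
              x$spec$n_params, x$result$best_fitness))
  invisible(x)
}

# Adam gradient refinement of a weight vector (optional post-step).
# Minibatch BCE with dropout and per-batch batch-norm statistics.
refine_with_adam <- function(spec, weights, X, y, epochs = 20L, lr = 1e-3,
                             batch_size = 32L, seed = 1L) {
  set.seed(as.integer(seed))
  w <- weights
  m <- numeric(length(w)); v <- numeric(length(w))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  n <- nrow(X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      if (length(idx) < 2L) next
      g <- dense_grad(spec, w, X[idx, , drop = FALSE], y[idx])
      losses <- c(losses, g$loss)
      t <- t + 1
      m <- b1 * m + (1 - b1) * g$grad
      v <- b2 * v + (1 - b2) * g$grad^2
      w <- w - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    }
    history[ep] <- mean(losses)
  }
  list(weights = w, history = history)
}

# Loss and gradient of the weighted BCE for one minibatch, with batch-stat
# batch norm and inverted dropout.
dense_grad <- function(spec, weights, X, y) {
  layers <- unflatten_weights(weights, spec)
  L <- length(spec$hidden)
  n <- nrow(X)
  acts <- list(); zns <- list(); vars <- list(); drops <- list()
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    if (spec$batch_norm) {
      mu <- colMeans(z); vv <- colMeans(sweep(z, 2, mu)^2)
      zn <- sweep(sweep(z, 2, mu), 2, sqrt(vv + BN_EPS), "/")
      vars[[l]] <- vv
    } else zn <- z
    h <- relu(zn)
    if (spec$dropout_rate > 0) {
      keep <- matrix(stats::runif(length(h)) >= spec$dropout_rate,
                     nrow(h), ncol(h))
      h <- h * keep / (1 - spec$dropout_rate)
      drops[[l]] <- keep
    }
    acts[[l]] <- a; zns[[l]] <- zn
    a <- h
  }
  lout <- layers[[L + 1L]]
  logits <- as.numeric(sweep(a %*% lout$W, 2, lout$b, "+"))
  p <- sigmoid(logits)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  wpos <- spec$class_weight
  loss <- mean(-(wpos * y * log(pc) + (1 - y) * log(1 - pc)))
  # d loss / d logit for weighted BCE
  dlogit <- (-(wpos * y * (1 - p)) + (1 - y) * p) / n

  grads <- vector("list", L + 1L)
  grads[[L + 1L]] <- list(W = crossprod(a, matrix(dlogit, ncol = 1)),
                          b = sum(dlogit))
  da <- matrix(dlogit, ncol = 1) %*% t(lout$W)
  for (l in rev(seq_len(L))) {
    if (spec$dropout_rate > 0) da <- da * drops[[l]] / (1 - spec$dropout_rate)
    dzn <- da * (zns[[l]] > 0)
    if (spec$batch_norm) {
      zn <- zns[[l]]; sd_ <- sqrt(vars[[l]] + BN_EPS)
      mean_d <- colMeans(dzn)
      mean_dzn <- colMeans(dzn * zn)
      dz <- sweep(sweep(dzn, 2, mean_d) - sweep(zn, 2, mean_dzn, "*"),
                  2, sd_, "/")
    } else dz <- dzn
    grads[[l]] <- list(W = crossprod(acts[[l]], dz), b = colSums(dz))
    if (l > 1L) da <- dz %*% t(layers[[l]]$W)
  }
  list(loss = loss, grad = flatten_weights(grads))
}
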