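# Two-output feed-forward networks with the balanced early-stopping
# training protocol.
#
# One hidden layer, sigmoid activations throughout, cross-entropy loss,
# mini-batch stochastic gradient descent with momentum. One training
# "repetition" is a single pass over a freshly drawn class-balanced sample
# of the training rows; after each repetition the AUC on the cross-training
# rows is recorded, and training continues for at least
# `max_stagnant_rounds` repetitions beyond the best recorded AUC. The model
# returned is the weight snapshot at that best repetition.

#' Network hyperparameter configuration
#'
#' Ranges mirror the search space of the method: 10-100 hidden units,
#' learning rate 0.005-0.1, momentum 0.01-0.3.
#'
#' @param hidden_units hidden-layer size, 10..100.
#' @param learning_rate SGD step size, 0.005..0.1.
#' @param momentum momentum coefficient, 0.01..0.3.
#' @param seed integer seed for weight init, balancing and shuffling.
#' @param max_stagnant_rounds keep training this many repetitions beyond
#'   the best cross-training AUC before stopping (>= 10).
#' @param max_repetitions hard cap on repetitions.
#' @param batch_size mini-batch size.
#' @return object of class `network_config`.
#' @export
network_config <- function(hidden_units = 10L, learning_rate = 0.1,
                           momentum = 0.3, seed = 1L,
                           max_stagnant_rounds = 150L, max_repetitions = 1000L,
                           batch_size = 32L) {
  stopifnot(hidden_units >= 10L, hidden_units <= 100L,
            learning_rate >= 0.005, learning_rate <= 0.1,
            momentum >= 0.01, momentum <= 0.3,
            max_stagnant_rounds >= 10L, max_repetitions >= 1L,
            batch_size >= 1L)
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed),
                 max_stagnant_rounds = as.integer(max_stagnant_rounds),
                 max_repetitions = as.integer(max_repetitions),
                 batch_size = as.integer(batch_size)),
            class = "network_config")
}

#' Class-balanced training subset
#'
#' Randomly down-samples the majority class to the minority count. The
#' protocol re-draws this subset at every training repetition, each draw
#' from its own seed in the configured seed sequence.
#'
#' @param labels character vector over {"neutral","effect"} (or 0/1).
#' @param seed integer seed.
#' @return integer row indices of the balanced subset (shuffled).
#' @export
balance_training_set <- function(labels, seed) {
  y <- if (is.numeric(labels)) as.integer(labels) else .label_to01(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to balance")
  m <- min(n1, n0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  idx <- c(sample(which(y == 1L), m), sample(which(y == 0L), m))
  sample(idx)
}

# Weight init: uniform in +/- 1/sqrt(fan-in).
.init_weights <- function(d, h, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  list(
    W1 = matrix(stats::runif((d + 1L) * h, -1, 1) / sqrt(d + 1), d + 1L, h),
    W2 = matrix(stats::runif((h + 1L) * 2L, -1, 1) / sqrt(h + 1), h + 1L, 2L)
  )
}

# Forward pass: returns n x 2 matrix of outputs (neutral, effect) in [0,1].
.nn_forward <- function(weights, x) {
  H <- .sigmoid(cbind(x, 1) %*% weights$W1)
  .sigmoid(cbind(H, 1) %*% weights$W2)
}

# One mini-batch SGD pass over rows `idx` of (x, targets). Mutates and
# returns weights and momentum velocities.
.nn_epoch <- function(weights, vel, x, targets, idx, lr, mom, batch_size) {
  nb <- ceiling(length(idx) / batch_size)
  for (b in seq_len(nb)) {
    rows <- idx[((b - 1L) * batch_size + 1L):min(b * batch_size, length(idx))]
    xb <- cbind(x[rows, , drop = FALSE], 1)
    tb <- targets[rows, , drop = FALSE]
    A1 <- xb %*% weights$W1
    H <- .sigmoid(A1)
    Hb <- cbind(H, 1)
    O <- .sigmoid(Hb %*% weights$W2)
    if (any(!is.finite(O)))
      stop("non-finite network output during training (exploding weights); ",
           "lower the learning rate")
    dO <- O - tb                                # cross-entropy x sigmoid'
    gW2 <- crossprod(Hb, dO) / nrow(xb)
    dH <- (dO %*% t(weights$W2[seq_len(ncol(H)), , drop = FALSE])) * H * (1 - H)
    gW1 <- crossprod(xb, dH) / nrow(xb)
    vel$W1 <- mom * vel$W1 - lr * gW1
    vel$W2 <- mom * vel$W2 - lr * gW2
    weights$W1 <- weights$W1 + vel$W1
    weights$W2 <- weights$W2 + vel$W2
  }
  list(weights = weights, vel = vel)
}

#' Train one two-output network with balanced early stopping
#'
#' Implements the anti-overfitting protocol: every repetition trains on a
#' freshly drawn class-balanced sample, the cross-training AUC is recorded
#' after each repetition, and training continues for at least
#' `max_stagnant_rounds` further repetitions beyond the best recorded AUC
#' before returning the snapshot with maximal cross-training AUC.
#'
#' @param x_train,y_train training feature matrix and labels
#'   ({"neutral","effect"} or 0/1).
#' @param x_crosstrain,y_crosstrain cross-training rows used only to record
#'   AUC and pick the stopping point.
#' @param config a [network_config()].
#' @return object of class `vep_network`: best-snapshot weights, training
#'   history (per-repetition cross-training AUC), best repetition and AUC.
#' @export
train_network <- function(x_train, y_train, x_crosstrain, y_crosstrain, config) {
  stopifnot(inherits(config, "network_config"),
            ncol(x_train) == ncol(x_crosstrain),
            nrow(x_train) > 0L, nrow(x_crosstrain) > 0L)
  y <- if (is.numeric(y_train)) as.integer(y_train) else .label_to01(y_train)
  yct <- if (is.numeric(y_crosstrain)) as.integer(y_crosstrain) else .label_to01(y_crosstrain)
  targets <- cbind(neutral = 1 - y, effect = y)

  weights <- .init_weights(ncol(x_train), config$hidden_units, config$seed)
  vel <- list(W1 = weights$W1 * 0, W2 = weights$W2 * 0)
  best <- list(auc = -Inf, rep = 0L, weights = weights)
  history <- numeric(0)

  for (r in seq_len(config$max_repetitions)) {
    idx <- balance_training_set(y, seed = .child_seed(config$seed, r))
    st <- .nn_epoch(weights, vel, x_train, targets, idx,
                    config$learning_rate, config$momentum, config$batch_size)
    weights <- st$weights; vel <- st$vel
    out <- .nn_forward(weights, x_crosstrain)
    auc <- rank_auc(out[, 2] - out[, 1], yct)
    history[r] <- auc
    if (auc > best$auc) best <- list(auc = auc, rep = r, weights = weights)
    if (r - best$rep >= config$max_stagnant_rounds) break
  }
  structure(list(weights = best$weights, config = config,
                 history = data.frame(repetition = seq_along(history),
                                      crosstrain_auc = history),
                 best_repetition = best$rep, best_auc = best$auc,
                 n_inputs = ncol(x_train)),
            class = "vep_network")
}

#' @export
print.vep_network <- function(x, ...) {
  cat(sprintf("vep_network: %d inputs, %d hidden units; best cross-training AUC %.3f at repetition %d/%d\n",
              x$n_inputs, x$config$hidden_units, x$best_auc,
              x$best_repetition, nrow(x$history)))
  invisible(x)
}

#' Raw outputs of a trained network
#'
#' @param object a `vep_network`.
#' @param x feature matrix with the training layout and normalization.
#' @param ... unused.
#' @return n x 2 matrix of (neutral, effect) outputs in [0, 1].
#' @export
predict.vep_network <- function(object, x, ...) {
  if (ncol(x) != object$n_inputs)
    stop(sprintf("feature layout mismatch: %d columns, network expects %d",
                 ncol(x), object$n_inputs))
  out <- .nn_forward(object$weights, x)
  colnames(out) <- c("neutral", "effect")
  out
}

#' Pick a network configuration by cross-training AUC
#'
#' Trains one network per grid point and returns the configuration with
#' maximal cross-training AUC. Ties are broken toward fewer hidden units,
#' then lower learning rate.
#'
#' @param x_train,y_train,x_crosstrain,y_crosstrain as in [train_network()].
#' @param grid list of [network_config()]s.
#' @return the winning `network_config`, with the winning AUC in attribute
#'   `"auc"`.
#' @export
hyperparameter_search <- function(x_train, y_train, x_crosstrain, y_crosstrain, grid) {
  if (length(grid) == 0L) stop("empty hyperparameter grid")
  aucs <- vapply(grid, function(cfg) {
    train_network(x_train, y_train, x_crosstrain, y_crosstrain, cfg)$best_auc
  }, numeric(1))
  hid <- vapply(grid, function(g) g$hidden_units, numeric(1))
  lr <- vapply(grid, function(g) g$learning_rate, numeric(1))
  best <- order(-aucs, hid, lr)[1]
  out <- grid[[best]]
  attr(out, "auc") <- aucs[best]
  out
}

#' Default coarse hyperparameter grid
#'
#' The stated ranges sampled coarsely: hidden units {10, 30, 50, 100},
#' learning rate {0.005, 0.01, 0.05, 0.1}, momentum {0.01, 0.1, 0.3}.
#'
#' @param seed seed given to every configuration.
#' @return list of [network_config()]s (48 points).
#' @export
default_grid <- function(seed = 1L) {
  pts <- expand.grid(h = c(10L, 30L, 50L, 100L),
                     lr = c(0.005, 0.01, 0.05, 0.1),
                     mom = c(0.01, 0.1, 0.3))
  lapply(seq_len(nrow(pts)), function(i)
    network_config(pts$h[i], pts$lr[i], pts$mom[i], seed = seed))
}

#' Reliability index of a prediction
#'
#' The gap between the two averaged output units, banded into integers:
#' `RI = floor(10 * |avg_effect - avg_neutral|)`, capped at 10. The display
#' digit shown to users caps at 9 (0 = least reliable, 9 = most reliable).
#'
#' @param avg_effect,avg_neutral averaged ensemble outputs in [0, 1].
#' @return data.frame with integer columns `ri` (0..10) and `digit` (0..9).
#' @examples
#' reliability_index(0.9, 0.1)  # ri 8
#' reliability_index(1, 0)      # ri 10, digit 9
#' @export
reliability_index <- function(avg_effect, avg_neutral) {
  if (any(avg_effect < 0 | avg_effect > 1 | avg_neutral < 0 | avg_neutral > 1))
    stop("averaged outputs must lie in [0, 1]")
  d <- abs(avg_effect - avg_neutral)
  ri <- pmin(as.integer(floor(10 * d + 1e-9)), 10L)  # 1e-9 guards fp noise at band edges
  data.frame(ri = ri, digit = pmin(ri, 9L))
}
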