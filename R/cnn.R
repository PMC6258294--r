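#' Configuration for the 1-D convolutional network
#'
#' The architecture is fixed at two convolutional layers, one flatten layer,
#' two dense layers and a two-unit softmax output; sigmoid activations on all
#' hidden layers; dropout and L2 weight decay on the dense layers; trained by
#' minimising categorical cross-entropy with the Adam optimiser. Only the
#' sizes and training hyperparameters are configurable.
#'
#' @param conv_channels integer(2): output channels of the two conv layers.
#' @param conv_kernels integer(2): kernel widths in sequence steps.
#' @param dense_units integer(2): units of the two dense layers.
#' @param dropout_rate dropout probability on dense activations, in [0, 1).
#' @param l2_lambda L2 penalty weight on dense-layer weights.
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param L encoded sequence length in steps (input width = L * 4 bits).
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return list of class \code{cnn_config}.
#' @export
cnn_config <- function(conv_channels = c(16L, 32L), conv_kernels = c(8L, 4L),
                       dense_units = c(64L, 32L), dropout_rate = 0.3,
                       l2_lambda = 1e-3, epochs = 100L, batch_size = 32L,
                       learning_rate = 1e-3, L = ONE_HOT_LENGTH, seed = 1L) {
  stopifnot(length(conv_channels) == 2, length(conv_kernels) == 2,
            length(dense_units) == 2,
            dropout_rate >= 0, dropout_rate < 1, l2_lambda >= 0,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  t1 <- L - conv_kernels[1] + 1
  t2 <- t1 - conv_kernels[2] + 1
  if (t2 < 1) stop("kernels too wide for input length L = ", L)
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernels = as.integer(conv_kernels),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, l2_lambda = l2_lambda,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, L = as.integer(L),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Glorot-uniform weight matrix
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# im2col for the first conv layer: X is n x (L*4) position-major one-hot;
# a width-k window over steps is contiguous in the flattened vector.
# Returns a (T*n) x (k*4) matrix, position-major (row (t-1)*n + i).
im2col_input <- function(X, k, T1) {
  n <- nrow(X)
  out <- matrix(0, T1 * n, k * 4L)
  for (t in seq_len(T1)) {
    out[(t - 1L) * n + seq_len(n), ] <-
      X[, ((t - 1L) * 4L + 1L):((t + k - 1L) * 4L), drop = FALSE]
  }
  out
}

# im2col between conv layers: A is (T_in*n) x c position-major activations.
im2col_hidden <- function(A, n, T_in, T_out, k, c) {
  out <- matrix(0, T_out * n, k * c)
  for (t in seq_len(T_out)) {
    for (j in seq_len(k)) {
      out[(t - 1L) * n + seq_len(n), ((j - 1L) * c + 1L):(j * c)] <-
        A[(t + j - 2L) * n + seq_len(n), , drop = FALSE]
    }
  }
  out
}

cnn_init_params <- function(cfg) {
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  k1 <- cfg$conv_kernels[1]; k2 <- cfg$conv_kernels[2]
  t2 <- cfg$L - k1 - k2 + 2L
  d1 <- cfg$dense_units[1]; d2 <- cfg$dense_units[2]
  list(W1 = glorot(k1 * 4L, c1), b1 = numeric(c1),
       W2 = glorot(k2 * c1, c2), b2 = numeric(c2),
       Wd1 = glorot(t2 * c2, d1), bd1 = numeric(d1),
       Wd2 = glorot(d1, d2), bd2 = numeric(d2),
       Wo = glorot(d2, 2L), bo = numeric(2L))
}

# Forward pass. Returns softmax probabilities and, if keep_cache, every
# intermediate needed by backprop. Dropout masks are applied only when given.
cnn_forward <- function(X, p, cfg, masks = NULL, keep_cache = FALSE) {
  n <- nrow(X)
  k1 <- cfg$conv_kernels[1]; k2 <- cfg$conv_kernels[2]
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  T1 <- cfg$L - k1 + 1L
  T2 <- T1 - k2 + 1L
  X1 <- im2col_input(X, k1, T1)
  A1 <- sigmoid(sweep(X1 %*% p$W1, 2, p$b1, "+"))
  X2 <- im2col_hidden(A1, n, T1, T2, k2, c1)
  A2 <- sigmoid(sweep(X2 %*% p$W2, 2, p$b2, "+"))
  flat <- matrix(0, n, T2 * c2)
  for (t in seq_len(T2)) {
    flat[, ((t - 1L) * c2 + 1L):(t * c2)] <- A2[(t - 1L) * n + seq_len(n), ,
                                                drop = FALSE]
  }
  H1 <- sigmoid(sweep(flat %*% p$Wd1, 2, p$bd1, "+"))
  if (!is.null(masks)) H1 <- H1 * masks$m1
  H2 <- sigmoid(sweep(H1 %*% p$Wd2, 2, p$bd2, "+"))
  if (!is.null(masks)) H2 <- H2 * masks$m2
  Z <- sweep(H2 %*% p$Wo, 2, p$bo, "+")
  Z <- Z - apply(Z, 1, max)
  probs <- exp(Z) / rowSums(exp(Z))
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs, X1 = X1, A1 = A1, X2 = X2, A2 = A2, flat = flat,
       H1 = H1, H2 = H2, n = n, T1 = T1, T2 = T2)
}

cnn_gradients <- function(cache, Y, p, cfg, masks) {
  n <- cache$n
  c1 <- cfg$conv_channels[1]; c2 <- cfg$conv_channels[2]
  k2 <- cfg$conv_kernels[2]
  T1 <- cache$T1; T2 <- cache$T2
  dZ <- (cache$probs - Y) / n
  g <- list()
  g$Wo <- crossprod(cache$H2, dZ)  # output layer carries no L2 penalty
  g$bo <- colSums(dZ)
  dH2 <- dZ %*% t(p$Wo)
  dH2 <- dH2 * masks$m2
  dZd2 <- dH2 * cache$H2 * (1 - cache$H2)
  g$Wd2 <- crossprod(cache$H1, dZd2) + cfg$l2_lambda * p$Wd2
  g$bd2 <- colSums(dZd2)
  dH1 <- dZd2 %*% t(p$Wd2)
  dH1 <- dH1 * masks$m1
  dZd1 <- dH1 * cache$H1 * (1 - cache$H1)
  g$Wd1 <- crossprod(cache$flat, dZd1) + cfg$l2_lambda * p$Wd1
  g$bd1 <- colSums(dZd1)
  dflat <- dZd1 %*% t(p$Wd1)
  dA2 <- matrix(0, T2 * n, c2)
  for (t in seq_len(T2)) {
    dA2[(t - 1L) * n + seq_len(n), ] <- dflat[, ((t - 1L) * c2 + 1L):(t * c2),
                                              drop = FALSE]
  }
  dZ2 <- dA2 * cache$A2 * (1 - cache$A2)
  g$W2 <- crossprod(cache$X2, dZ2)
  g$b2 <- colSums(dZ2)
  dX2 <- dZ2 %*% t(p$W2)
  dA1 <- matrix(0, T1 * n, c1)
  for (t in seq_len(T2)) {
    for (j in seq_len(k2)) {
      rows <- (t + j - 2L) * n + seq_len(n)
      dA1[rows, ] <- dA1[rows, , drop = FALSE] +
        dX2[(t - 1L) * n + seq_len(n), ((j - 1L) * c1 + 1L):(j * c1),
            drop = FALSE]
    }
  }
  dZ1 <- dA1 * cache$A1 * (1 - cache$A1)
  g$W1 <- crossprod(cache$X1, dZ1)
  g$b1 <- colSums(dZ1)
  g
}

#' Train the 1-D convolutional network
#'
#' Input rows are one-hot encoded sequences (position-major 4-bit blocks,
#' width \code{L * 4}); the network reads them as an L-step, 4-channel 1-D
#' signal. Training minimises categorical cross-entropy (plus L2 on the
#' dense-layer weights) with Adam; dropout is applied to the two dense
#' layers' activations during training only. Fully deterministic given the
#' config seed.
#'
#' @param encoded binary matrix n x (L*4) from \code{one_hot_matrix}.
#' @param labels binary vector (1 = positive).
#' @param config \code{cnn_config}.
#' @return list of class \code{cnn_model} with fitted parameters, the config
#'   and the per-epoch training loss.
#' @export
train_cnn <- function(encoded, labels, config = cnn_config()) {
  if (ncol(encoded) != config$L * 4L) {
    stop("input width ", ncol(encoded), " != L*4 = ", config$L * 4L)
  }
  if (length(unique(labels)) < 2) stop("both classes must be present")
  stopifnot(nrow(encoded) == length(labels))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  p <- cnn_init_params(config)
  m <- lapply(p, function(x) x * 0)
  v <- lapply(p, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  n <- nrow(encoded)
  Y_full <- cbind(1 - labels, labels)
  step <- 0L
  losses <- numeric(config$epochs)
  keep <- 1 - config$dropout_rate
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      b <- idx[start:min(start + config$batch_size - 1L, n)]
      Xb <- encoded[b, , drop = FALSE]
      Yb <- Y_full[b, , drop = FALSE]
      masks <- if (config$dropout_rate > 0) {
        list(m1 = matrix(stats::rbinom(length(b) * config$dense_units[1],
                                       1, keep) / keep,
                         length(b), config$dense_units[1]),
             m2 = matrix(stats::rbinom(length(b) * config$dense_units[2],
                                       1, keep) / keep,
                         length(b), config$dense_units[2]))
      } else {
        list(m1 = 1, m2 = 1)
      }
      cache <- cnn_forward(Xb, p, config, masks = masks, keep_cache = TRUE)
      epoch_loss <- epoch_loss -
        sum(Yb * log(pmax(cache$probs, 1e-12))) / length(b)
      grads <- cnn_gradients(cache, Yb, p, config, masks)
      step <- step + 1L
      for (nm in names(p)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^step)
        vhat <- v[[nm]] / (1 - beta2^step)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    losses[epoch] <- epoch_loss / ceiling(n / config$batch_size)
  }
  structure(list(params = p, config = config, loss = losses),
            class = "cnn_model")
}

#' Positive-class probabilities from a trained CNN
#'
#' @param object \code{cnn_model}.
#' @param encoded binary matrix n x (L*4).
#' @param ... unused.
#' @return numeric vector of softmax positive-class probabilities.
#' @export
predict.cnn_model <- function(object, encoded, ...) {
  if (ncol(encoded) != object$config$L * 4L) {
    stop("input width ", ncol(encoded), " != L*4 = ", object$config$L * 4L)
  }
  out <- numeric(nrow(encoded))
  # chunked to bound the im2col working set
  chunk <- 2048L
  for (start in seq(1L, nrow(encoded), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(encoded))
    out[rows] <- cnn_forward(encoded[rows, , drop = FALSE], object$params,
                             object$config)$probs[, 2]
  }
  out
}

#' Seeded random search over CNN hyperparameters
#'
#' Draws \code{n_trials} configurations uniformly from the supplied value
#' grids, trains each on a stratified internal split of the training data,
#' and returns the configuration with the best validation AUC. A lightweight
#' stand-in for full Bayesian hyperparameter optimisation: the architecture
#' (2 conv + 2 dense + softmax) is fixed, only sizes and regularisation move.
#'
#' @param encoded one-hot training matrix n x (L*4).
#' @param labels binary vector (1 = positive).
#' @param n_trials number of sampled configurations.
#' @param val_fraction fraction of each class held out internally for
#'   scoring trials.
#' @param grid named list of candidate values; elements
#'   \code{conv_channels}, \code{conv_kernels}, \code{dense_units} are lists
#'   of length-2 vectors, \code{dropout_rate}, \code{l2_lambda},
#'   \code{learning_rate} numeric vectors.
#' @param epochs training epochs per trial.
#' @param seed RNG seed for sampling and every trial fit.
#' @return list with \code{best} (a \code{cnn_config}) and \code{trials}
#'   (data.frame of sampled settings and validation AUC).
#' @export
tune_cnn_random <- function(encoded, labels, n_trials = 10L,
                            val_fraction = 0.2,
                            grid = list(
                              conv_channels = list(c(8L, 16L), c(16L, 32L)),
                              conv_kernels = list(c(6L, 3L), c(8L, 4L)),
                              dense_units = list(c(32L, 16L), c(64L, 32L)),
                              dropout_rate = c(0.2, 0.3, 0.5),
                              l2_lambda = c(1e-4, 1e-3, 1e-2),
                              learning_rate = c(1e-3, 3e-3)),
                            epochs = 30L, seed = 1L) {
  stopifnot(n_trials >= 1, val_fraction > 0, val_fraction < 0.5)
  idx_pos <- which(labels == 1)
  idx_neg <- which(labels == 0)
  if (length(idx_pos) < 5 || length(idx_neg) < 5) {
    stop("too few samples per class to tune")
  }
  with_seed(seed, {
    val <- c(sample(idx_pos, max(1, round(val_fraction * length(idx_pos)))),
             sample(idx_neg, max(1, round(val_fraction * length(idx_neg)))))
    tr <- setdiff(seq_along(labels), val)
    pick <- function(x) x[[sample.int(length(x), 1)]]
    trials <- vector("list", n_trials)
    best <- NULL
    best_auc <- -Inf
    for (t in seq_len(n_trials)) {
      cfg <- cnn_config(conv_channels = pick(grid$conv_channels),
                        conv_kernels = pick(grid$conv_kernels),
                        dense_units = pick(grid$dense_units),
                        dropout_rate = pick(as.list(grid$dropout_rate)),
                        l2_lambda = pick(as.list(grid$l2_lambda)),
                        learning_rate = pick(as.list(grid$learning_rate)),
                        epochs = epochs, seed = seed + t)
      fit <- train_cnn(encoded[tr, , drop = FALSE], labels[tr], cfg)
      auc <- auc_rank(predict(fit, encoded[val, , drop = FALSE]), labels[val])
      trials[[t]] <- data.frame(
        trial = t, conv1 = cfg$conv_channels[1], conv2 = cfg$conv_channels[2],
        kernel1 = cfg$conv_kernels[1], kernel2 = cfg$conv_kernels[2],
        dense1 = cfg$dense_units[1], dense2 = cfg$dense_units[2],
        dropout = cfg$dropout_rate, l2 = cfg$l2_lambda,
        lr = cfg$learning_rate, val_auc = auc)
      if (auc > best_auc) { best_auc <- auc; best <- cfg }
    }
    list(best = best, trials = do.call(rbind, trials))
  })
}
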