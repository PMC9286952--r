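#' DBN training configuration
#'
#' A deep belief network here is a stack of Bernoulli restricted Boltzmann
#' machines pretrained layer by layer with contrastive divergence, topped by
#' a 2-unit softmax output layer and fine-tuned end-to-end by
#' backpropagation. Continuous inputs are min-max scaled to `[0,1]` and
#' treated as visible-unit probabilities.
#'
#' @param layers hidden-layer widths, bottom to top (default `c(64, 32)`).
#' @param alpha learning rate for both pretraining and fine-tuning
#'   (default 0.1).
#' @param batch_size minibatch size (default 16; clipped to the training
#'   set size at fit time).
#' @param pretrain_epochs CD epochs per layer (default 50).
#' @param finetune_epochs backpropagation epochs (default 100).
#' @param cd_steps Gibbs steps per CD update (default 1).
#' @param sample_hidden sample binary hidden states on the data-to-hidden
#'   pass (default TRUE); probabilities are used everywhere else.
#' @param momentum classical momentum of the fine-tuning phase (default
#'   0.9; 0 disables it). Without it the small symmetric initial weights
#'   leave a deep sigmoid stack on the flat part of the loss for far more
#'   epochs than desk-scale budgets allow.
#' @param seed optional integer seed for weight init, shuffling and
#'   sampling.
#' @return a list of class `dbn_config`.
#' @export
dbn_config <- function(layers = c(64L, 32L), alpha = 0.1, batch_size = 16L,
                       pretrain_epochs = 50L, finetune_epochs = 100L,
                       cd_steps = 1L, sample_hidden = TRUE, momentum = 0.9,
                       seed = NULL) {
  stopifnot(alpha > 0, batch_size >= 1, pretrain_epochs >= 0,
            finetune_epochs >= 0, cd_steps >= 1, all(layers >= 1),
            momentum >= 0, momentum < 1)
  structure(list(layers = as.integer(layers), alpha = alpha,
                 batch_size = as.integer(batch_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 cd_steps = as.integer(cd_steps),
                 sample_hidden = isTRUE(sample_hidden),
                 momentum = momentum, seed = seed),
            class = "dbn_config")
}

#' Initialize RBM parameters
#'
#' Weights drawn from Normal(0, 0.01), biases zero.
#'
#' @param n_visible,n_hidden layer widths.
#' @return a list of class `rbm_params` with `W` (`n_visible x n_hidden`),
#'   visible bias `a`, hidden bias `b`.
#' @export
rbm_init <- function(n_visible, n_hidden) {
  structure(list(W = matrix(stats::rnorm(n_visible * n_hidden, 0, 0.01),
                            n_visible, n_hidden),
                 a = numeric(n_visible), b = numeric(n_hidden)),
            class = "rbm_params")
}

#' RBM energy
#'
#' `E(v,h) = -sum_ij W_ij v_i h_j - sum_i a_i v_i - sum_j b_j h_j`.
#'
#' @param params an `rbm_params`.
#' @param v,h visible and hidden state vectors.
#' @return scalar energy.
#' @export
rbm_energy <- function(params, v, h) {
  if (length(v) != nrow(params$W) || length(h) != ncol(params$W)) {
    stop("state dimensions do not match the parameter shapes")
  }
  -as.numeric(t(v) %*% params$W %*% h) - sum(params$a * v) -
    sum(params$b * h)
}

#' Hidden activation probabilities given visible states
#'
#' `P(h_j = 1 | v) = sigmoid(sum_i W_ij v_i + b_j)` applied row-wise.
#'
#' @param params an `rbm_params`.
#' @param V matrix of visible rows (a vector is treated as one row).
#' @return matrix of probabilities in (0,1).
#' @export
hidden_given_visible <- function(params, V) {
  V <- matrix(V, ncol = nrow(params$W))
  sigmoid(add_bias(V %*% params$W, params$b))
}

#' Visible activation probabilities given hidden states
#'
#' `P(v_i = 1 | h) = sigmoid(sum_j W_ij h_j + a_i)` applied row-wise.
#'
#' @param params an `rbm_params`.
#' @param H matrix of hidden rows (a vector is treated as one row).
#' @return matrix of probabilities in (0,1).
#' @export
visible_given_hidden <- function(params, H) {
  H <- matrix(H, ncol = ncol(params$W))
  sigmoid(add_bias(H %*% t(params$W), params$a))
}

#' One contrastive-divergence update
#'
#' CD-k with the standard variance-reduction choices: the data-to-hidden
#' pass samples binary hidden states (unless `sample_hidden = FALSE`),
#' reconstructions use activation probabilities, and the gradient is the
#' batch mean of `<v h'>_data - <v h'>_recon`, scaled by the learning rate.
#'
#' @param params an `rbm_params`.
#' @param batch matrix of visible rows in `[0,1]`.
#' @param alpha learning rate.
#' @param cd_steps Gibbs steps (default 1).
#' @param sample_hidden sample hidden states on the data pass.
#' @return the updated `rbm_params`.
#' @export
cd1_update <- function(params, batch, alpha, cd_steps = 1L,
                       sample_hidden = TRUE) {
  batch <- matrix(batch, ncol = nrow(params$W))
  nb <- nrow(batch)
  if (nb == 0L) stop("empty batch")
  ph0 <- hidden_given_visible(params, batch)
  h <- if (sample_hidden) {
    (matrix(stats::runif(length(ph0)), nrow(ph0)) < ph0) * 1
  } else ph0
  v1 <- batch
  for (s in seq_len(cd_steps)) {
    v1 <- visible_given_hidden(params, h)
    ph1 <- hidden_given_visible(params, v1)
    if (s < cd_steps) {
      h <- if (sample_hidden) {
        (matrix(stats::runif(length(ph1)), nrow(ph1)) < ph1) * 1
      } else ph1
    }
  }
  params$W <- params$W + alpha * (crossprod(batch, ph0) -
                                    crossprod(v1, ph1)) / nb
  params$a <- params$a + alpha * (colMeans(batch) - colMeans(v1))
  params$b <- params$b + alpha * (colMeans(ph0) - colMeans(ph1))
  params
}

# Train one RBM on data rows in [0,1].
rbm_train <- function(X, n_hidden, epochs, alpha, batch_size,
                      cd_steps = 1L, sample_hidden = TRUE) {
  params <- rbm_init(ncol(X), n_hidden)
  n <- nrow(X)
  bs <- min(batch_size, n)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = bs)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1, n)]
      params <- cd1_update(params, X[idx, , drop = FALSE], alpha,
                           cd_steps, sample_hidden)
    }
  }
  params
}

#' Greedy layer-wise pretraining
#'
#' Trains the RBM stack bottom-up; layer `k` is trained on the hidden
#' activation probabilities of layer `k - 1`.
#'
#' @param X data matrix scaled to `[0,1]`.
#' @param config a [dbn_config()]. The active RNG stream is used (seed the
#'   caller or use [dbn_train()]).
#' @return list of `rbm_params`, bottom to top.
#' @export
dbn_pretrain <- function(X, config = dbn_config()) {
  input <- X
  rbms <- vector("list", length(config$layers))
  for (k in seq_along(config$layers)) {
    rbms[[k]] <- if (config$pretrain_epochs > 0) {
      rbm_train(input, config$layers[k], config$pretrain_epochs,
                config$alpha, config$batch_size, config$cd_steps,
                config$sample_hidden)
    } else {
      rbm_init(ncol(input), config$layers[k])
    }
    input <- hidden_given_visible(rbms[[k]], input)
  }
  rbms
}

# Forward pass through the sigmoid stack; returns list of activations per
# layer (including the input) plus softmax output probabilities.
dbn_forward <- function(weights, X) {
  acts <- vector("list", length(weights$W) + 1)
  acts[[1]] <- X
  for (k in seq_along(weights$W)) {
    acts[[k + 1]] <- sigmoid(add_bias(acts[[k]] %*% weights$W[[k]],
                                      weights$b[[k]]))
  }
  Z <- add_bias(acts[[length(acts)]] %*% weights$W_out, weights$b_out)
  Z <- Z - pmax(Z[, 1], Z[, 2])   # softmax shift; output layer has 2 units
  E <- exp(Z)
  P <- E / rowSums(E)
  list(acts = acts, P = P)
}

#' Train a deep belief network classifier
#'
#' Min-max scales the features to `[0,1]`, pretrains the RBM stack with
#' contrastive divergence, then attaches a 2-unit softmax output layer and
#' fine-tunes all layers by minibatch backpropagation on the cross-entropy
#' loss.
#'
#' @param X numeric feature matrix (raw scale).
#' @param y binary labels (0/1).
#' @param config a [dbn_config()].
#' @return an object of class `dbn_model`.
#' @export
dbn_train <- function(X, y, config = dbn_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training data contain a single class")
  if (!is.null(config$seed)) set.seed(config$seed)
  rng <- list(min = apply(X, 2, min), max = apply(X, 2, max))
  Xs <- scale01(X, rng)
  rbms <- dbn_pretrain(Xs, config)
  weights <- list(W = lapply(rbms, `[[`, "W"),
                  b = lapply(rbms, `[[`, "b"),
                  W_out = matrix(stats::rnorm(utils::tail(config$layers, 1) * 2,
                                              0, 0.1),
                                 utils::tail(config$layers, 1), 2),
                  b_out = numeric(2))
  n <- nrow(Xs)
  bs <- min(config$batch_size, n)
  Y <- cbind(1 - y, y)   # one-hot, column 2 = positive class
  vel <- rapply(weights, function(m) m * 0, how = "replace")
  mom <- config$momentum
  for (ep in seq_len(config$finetune_epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = bs)) {
      idx <- ord[s:min(s + bs - 1, n)]
      g <- backprop_grad(weights, Xs[idx, , drop = FALSE],
                         Y[idx, , drop = FALSE])
      for (k in seq_along(weights$W)) {
        vel$W[[k]] <- mom * vel$W[[k]] + g$W[[k]]
        weights$W[[k]] <- weights$W[[k]] - config$alpha * vel$W[[k]]
        vel$b[[k]] <- mom * vel$b[[k]] + g$b[[k]]
        weights$b[[k]] <- weights$b[[k]] - config$alpha * vel$b[[k]]
      }
      vel$W_out <- mom * vel$W_out + g$W_out
      weights$W_out <- weights$W_out - config$alpha * vel$W_out
      vel$b_out <- mom * vel$b_out + g$b_out
      weights$b_out <- weights$b_out - config$alpha * vel$b_out
    }
  }
  structure(list(weights = weights, scaling = rng, config = config,
                 classes = c(0L, 1L)),
            class = "dbn_model")
}

scale01 <- function(X, rng) {
  span <- rng$max - rng$min
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2, rng$min, "-"), 2, span, "/")
  Xs <- pmin(pmax(Xs, 0), 1)
  dimnames(Xs) <- NULL
  Xs
}

# Cross-entropy gradients of the full stack for one minibatch (batch-mean
# scale), same list layout as the weights.
backprop_grad <- function(w, Xb, Yb) {
  nb <- nrow(Xb)
  fwd <- dbn_forward(w, Xb)
  acts <- fwd$acts
  L <- length(w$W)
  dZ <- (fwd$P - Yb) / nb
  g <- list(W = vector("list", L), b = vector("list", L),
            W_out = crossprod(acts[[L + 1]], dZ), b_out = colSums(dZ))
  dA <- dZ %*% t(w$W_out)
  for (k in L:1) {
    dZk <- dA * acts[[k + 1]] * (1 - acts[[k + 1]])
    g$W[[k]] <- crossprod(acts[[k]], dZk)
    g$b[[k]] <- colSums(dZk)
    if (k > 1) dA <- dZk %*% t(w$W[[k]])
  }
  g
}

#' @export
print.dbn_model <- function(x, ...) {
  cat(sprintf("<dbn_model> %d -> %s -> 2 (alpha = %g, batch = %d)\n",
              nrow(x$weights$W[[1]]),
              paste(x$config$layers, collapse = " -> "),
              x$config$alpha, x$config$batch_size))
  invisible(x)
}

#' Predict with a trained DBN
#'
#' @param object a `dbn_model`.
#' @param newdata feature matrix on the raw scale.
#' @param type `"class"` for 0/1 labels, `"prob"` for the positive-class
#'   probability.
#' @param ... unused.
#' @return integer labels or numeric probabilities.
#' @export
predict.dbn_model <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  Xs <- scale01(as.matrix(newdata), object$scaling)
  P <- dbn_forward(object$weights, Xs)$P
  if (type == "prob") P[, 2] else as.integer(P[, 2] > P[, 1])
}

#' Stratified k-fold cross-validation of a DBN
#'
#' @param table a [feature_table()].
#' @param config a [dbn_config()].
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling fold assignment and each fold's
#'   training randomness.
#' @return list with `fold_accuracy`, `mean_accuracy` and the fold ids.
#' @export
dbn_cv <- function(table, config = dbn_config(), folds = 10L, seed = 1L) {
  fold_id <- stratified_folds(table$labels, folds,
                              seed = derive_seed(seed, "dbn-cv-folds"))
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    te <- fold_id == f
    cfg <- config
    cfg$seed <- derive_seed(seed, "dbn-cv-fit", f)
    model <- dbn_train(table$values[!te, , drop = FALSE],
                       table$labels[!te], cfg)
    pred <- predict(model, table$values[te, , drop = FALSE])
    acc[f] <- mean(pred == table$labels[te])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc), fold_id = fold_id)
}

#' Save a trained DBN to a JSON archive
#'
#' Serializes weights, biases, input scaling, configuration and class
#' labels into a single portable JSON file.
#'
#' @param model a `dbn_model`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_dbn <- function(model, path) {
  payload <- list(
    W = model$weights$W,
    b = model$weights$b,
    W_out = model$weights$W_out,
    b_out = model$weights$b_out,
    scaling = model$scaling,
    config = model$config[c("layers", "alpha", "batch_size",
                            "pretrain_epochs", "finetune_epochs",
                            "cd_steps", "sample_hidden", "momentum",
                            "seed")],
    classes = model$classes
  )
  writeLines(jsonlite::toJSON(payload, digits = NA, null = "null"), path)
  invisible(path)
}

#' Load a DBN from a JSON archive
#'
#' @param path file written by [save_dbn()].
#' @return a `dbn_model`.
#' @export
load_dbn <- function(path) {
  p <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                          simplifyVector = TRUE)
  W <- lapply(p$W, function(m) matrix(as.numeric(m), nrow(m), ncol(m)))
  W_out <- matrix(as.numeric(p$W_out), nrow(p$W_out), ncol(p$W_out))
  cfg_in <- lapply(p$config, unlist)
  cfg <- do.call(dbn_config, cfg_in[!vapply(cfg_in, is.null, logical(1))])
  structure(list(weights = list(W = W, b = lapply(p$b, as.numeric),
                                W_out = W_out,
                                b_out = as.numeric(p$b_out)),
                 scaling = list(min = as.numeric(p$scaling$min),
                                max = as.numeric(p$scaling$max)),
                 config = cfg, classes = as.integer(p$classes)),
            class = "dbn_model")
}
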