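#' Training configuration
#'
#' Collects every tunable of the autoencoder and classifier training
#' stages. The defaults are the fixed hyperparameter settings of the
#' method: a single hidden layer of 512 ReLU units, L2 weight penalty
#' 1e-4, dropout 0.14, batch size 128, the Adam optimizer, mean squared
#' error for autoencoder pre-training and (class-weighted) binary
#' cross-entropy for the classifier.
#'
#' @param hidden_dims Integer vector of hidden layer widths; more than
#'   one entry requests greedy layerwise (stacked) pre-training.
#' @param activation Hidden activation: `"relu"`, `"linear"` or
#'   `"sigmoid"`.
#' @param l2 L2 weight-decay coefficient applied to all weight matrices.
#' @param dropout Dropout rate on hidden-layer outputs, active during
#'   both pre-training and fine-tuning.
#' @param batch_size Mini-batch size.
#' @param optimizer `"adam"` (default; beta1 0.9, beta2 0.999) or
#'   `"sgd"`.
#' @param learning_rate Optimizer step size.
#' @param init_stddev Standard deviation of the truncated-normal weight
#'   initializer (truncation at two standard deviations).
#' @param max_epochs Upper bound on training epochs.
#' @param early_stop_patience Epochs without improvement of the
#'   monitored quantity before training stops (best weights restored).
#' @param pos_weight Weight `w` of the positive-sample term of the
#'   classifier loss; must lie strictly between 0 and 1. See
#'   [weighted_bce()].
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; a full training run is reproducible given the seed.
#' @return A `training_config` list.
#' @export
training_config <- function(hidden_dims = 512L,
                            activation = c("relu", "linear", "sigmoid"),
                            l2 = 1e-4,
                            dropout = 0.14,
                            batch_size = 128L,
                            optimizer = c("adam", "sgd"),
                            learning_rate = 1e-3,
                            init_stddev = 0.05,
                            max_epochs = 100L,
                            early_stop_patience = 10L,
                            pos_weight = 0.5,
                            seed = 1L) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  stopifnot(all(hidden_dims >= 1L), batch_size >= 1L, init_stddev > 0,
            max_epochs >= 1L, early_stop_patience >= 1L)
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1)")
  if (pos_weight <= 0 || pos_weight >= 1) {
    abort("`pos_weight` must lie strictly inside (0, 1)")
  }
  structure(
    list(
      hidden_dims = as.integer(hidden_dims), activation = activation,
      l2 = l2, dropout = dropout, batch_size = as.integer(batch_size),
      optimizer = optimizer, learning_rate = learning_rate,
      init_stddev = init_stddev, max_epochs = as.integer(max_epochs),
      early_stop_patience = as.integer(early_stop_patience),
      pos_weight = pos_weight, seed = as.integer(seed)
    ),
    class = "training_config"
  )
}

#' Truncated-normal weight initializer
#'
#' Draws i.i.d. values from `Normal(0, stddev^2)`, redrawing any value
#' that falls outside two standard deviations of the mean.
#'
#' @param shape Integer vector: `c(rows, cols)` for a matrix or a single
#'   length for a vector.
#' @param stddev Standard deviation before truncation.
#' @param seed Optional seed for reproducible draws.
#' @return A matrix (or vector) of the requested shape.
#' @export
init_truncated_normal <- function(shape, stddev = 0.05, seed = NULL) {
  stopifnot(stddev > 0, length(shape) %in% c(1L, 2L))
  n <- prod(shape)
  .with_seed(seed, {
    x <- stats::rnorm(n, 0, stddev)
    bad <- which(abs(x) > 2 * stddev)
    while (length(bad) > 0L) {
      x[bad] <- stats::rnorm(length(bad), 0, stddev)
      bad <- bad[abs(x[bad]) > 2 * stddev]
    }
    if (length(shape) == 2L) matrix(x, shape[1L], shape[2L]) else x
  })
}

#' Class-weighted binary cross-entropy
#'
#' The classifier training loss
#' \deqn{L = -\sum_k \left( w\, y_k \log a_k + (1-w)(1-y_k)\log(1-a_k)\right)}
#' where `y_k` is the binary label, `a_k` the predicted positive-class
#' probability and `w` the weight of the positive-sample term.
#' Probabilities are clipped to `[1e-7, 1 - 1e-7]` before taking logs.
#' At `w = 0.5` the loss equals exactly half the standard (unweighted)
#' cross-entropy sum.
#'
#' @param labels Binary 0/1 vector.
#' @param probabilities Predicted probabilities.
#' @param pos_weight Positive-term weight `w`, strictly inside (0, 1).
#' @param reduction `"sum"` (the definition above, default) or `"mean"`
#'   (sum divided by the number of samples, the per-batch form used
#'   during optimization).
#' @return The loss value.
#' @examples
#' weighted_bce(c(1, 0), c(0.9, 0.2), pos_weight = 0.7)
#' @export
weighted_bce <- function(labels, probabilities, pos_weight = 0.5,
                         reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  labels <- .check_labels(labels, "labels")
  if (pos_weight <= 0 || pos_weight >= 1) {
    abort("`pos_weight` must lie strictly inside (0, 1)")
  }
  eps <- 1e-7
  a <- pmin(pmax(probabilities, eps), 1 - eps)
  terms <- pos_weight * labels * log(a) +
    (1 - pos_weight) * (1 - labels) * log(1 - a)
  total <- -sum(terms)
  if (reduction == "mean") total / length(labels) else total
}

# ---- internal layer plumbing -----------------------------------------

# descriptor matrix stripped of dimnames, so backprop products never
# drag row/column names into the weight matrices
.unnamed_features <- function(data) {
  m <- feature_matrix(data)
  dimnames(m) <- NULL
  m
}

.activate <- function(z, activation) {
  switch(activation,
    relu = pmax(z, 0),
    linear = z,
    sigmoid = 1 / (1 + exp(-z)),
    abort(sprintf("unknown activation '%s'", activation))
  )
}

.activate_grad <- function(z, activation) {
  switch(activation,
    relu = (z > 0) * 1,
    linear = 1,
    sigmoid = {
      s <- 1 / (1 + exp(-z))
      s * (1 - s)
    },
    abort(sprintf("unknown activation '%s'", activation))
  )
}

.new_layer <- function(input_dim, output_dim, activation, stddev,
                       seed = NULL) {
  list(
    W = init_truncated_normal(c(input_dim, output_dim), stddev, seed),
    b = numeric(output_dim),
    activation = activation
  )
}

# Forward pass. Returns per-layer pre-activations `z`, activations `a`
# (a[[1]] is the input) and, in training mode, the inverted-dropout
# masks applied to hidden-layer outputs.
.nn_forward <- function(layers, X, dropout = 0, training = FALSE) {
  n_layers <- length(layers)
  a <- vector("list", n_layers + 1L)
  z <- vector("list", n_layers)
  masks <- vector("list", n_layers)
  a[[1L]] <- X
  for (l in seq_len(n_layers)) {
    ly <- layers[[l]]
    z[[l]] <- sweep(a[[l]] %*% ly$W, 2L, ly$b, "+")
    out <- .activate(z[[l]], ly$activation)
    if (training && dropout > 0 && l < n_layers) {
      keep <- matrix(stats::runif(length(out)) >= dropout,
                     nrow(out), ncol(out))
      masks[[l]] <- keep / (1 - dropout)
      out <- out * masks[[l]]
    }
    a[[l + 1L]] <- out
  }
  list(a = a, z = z, masks = masks)
}

# Loss and analytic gradients for one batch.
# loss = "wbce": mean class-weighted BCE over the batch (sigmoid output);
# loss = "mse":  mean squared reconstruction error over all entries.
# Both get l2 * sum(W^2) added across every weight matrix.
.nn_loss_grad <- function(layers, X, target, loss, pos_weight = 0.5,
                          l2 = 0, dropout = 0, training = FALSE,
                          want_grad = TRUE) {
  fwd <- .nn_forward(layers, X, dropout, training)
  n_layers <- length(layers)
  n <- nrow(X)
  out <- fwd$a[[n_layers + 1L]]
  if (loss == "wbce") {
    y <- as.numeric(target)
    data_loss <- weighted_bce(y, as.numeric(out), pos_weight,
                              reduction = "mean")
    # d(mean wbce)/dz for a sigmoid output unit, unclipped form
    delta <- matrix(
      -(pos_weight * y * (1 - out) - (1 - pos_weight) * (1 - y) * out) / n,
      n, 1L
    )
  } else if (loss == "mse") {
    resid <- out - target
    data_loss <- mean(resid^2)
    delta <- 2 * resid / length(resid)
  } else {
    abort(sprintf("unknown loss '%s'", loss))
  }
  penalty <- if (l2 > 0) {
    l2 * sum(vapply(layers, function(ly) sum(ly$W^2), numeric(1)))
  } else 0
  total <- data_loss + penalty
  if (!want_grad) return(list(loss = total))

  grads <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    ly <- layers[[l]]
    if (l < n_layers) {
      nxt <- layers[[l + 1L]]
      delta <- delta %*% t(nxt$W)
      delta <- delta * .activate_grad(fwd$z[[l]], ly$activation)
      if (!is.null(fwd$masks[[l]])) delta <- delta * fwd$masks[[l]]
    }
    # for the output layer, delta already includes the activation grad
    gW <- crossprod(fwd$a[[l]], delta)
    if (l2 > 0) gW <- gW + 2 * l2 * ly$W
    grads[[l]] <- list(W = gW, b = colSums(delta))
  }
  list(loss = total, grads = grads)
}

# The output-layer delta folds the activation derivative in for wbce
# (sigmoid output) and mse (linear output); hidden layers multiply
# their own activation gradient explicitly during backpropagation.
.adam_state <- function(layers) {
  lapply(layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0,
    mb = ly$b * 0, vb = ly$b * 0
  ))
}

.optimizer_step <- function(layers, grads, state, t, cfg) {
  lr <- cfg$learning_rate
  if (cfg$optimizer == "sgd") {
    for (l in seq_along(layers)) {
      layers[[l]]$W <- layers[[l]]$W - lr * grads[[l]]$W
      layers[[l]]$b <- layers[[l]]$b - lr * grads[[l]]$b
    }
    return(list(layers = layers, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (l in seq_along(layers)) {
    g <- grads[[l]]
    s <- state[[l]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[l]]$b <- layers[[l]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[l]] <- s
  }
  list(layers = layers, state = state)
}

# Mini-batch training shared by the autoencoder and classifier stages.
# monitor_fun(layers) returns the quantity tracked for early stopping;
# `maximize` says which direction is an improvement. When monitor_fun is
# NULL the epoch training loss is monitored (minimized). Best-so-far
# weights are restored on exit.
.nn_train <- function(layers, X, target, loss, cfg, monitor_fun = NULL,
                      maximize = FALSE) {
  n <- nrow(X)
  state <- .adam_state(layers)
  t_step <- 0L
  trace <- vector("list", cfg$max_epochs)
  best_layers <- layers
  best_metric <- if (maximize) -Inf else Inf
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      rows <- idx[s:min(s + cfg$batch_size - 1L, n)]
      lg <- .nn_loss_grad(layers, X[rows, , drop = FALSE],
                          if (is.matrix(target)) target[rows, , drop = FALSE]
                          else target[rows],
                          loss, cfg$pos_weight, cfg$l2, cfg$dropout,
                          training = TRUE)
      if (!is.finite(lg$loss)) {
        abort(sprintf(
          "non-finite training loss at epoch %d (loss=%g); check input scaling",
          epoch, lg$loss))
      }
      step <- .optimizer_step(layers, lg$grads, state, t_step <- t_step + 1L,
                              cfg)
      layers <- step$layers
      state <- step$state
      epoch_loss <- epoch_loss + lg$loss * length(rows)
    }
    epoch_loss <- epoch_loss / n
    metric <- if (is.null(monitor_fun)) epoch_loss else monitor_fun(layers)
    improved <- if (maximize) metric > best_metric else metric < best_metric
    if (improved) {
      best_metric <- metric
      best_layers <- layers
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace[[epoch]] <- tibble(epoch = epoch, loss = epoch_loss,
                             monitored = metric)
    if (stall >= cfg$early_stop_patience) break
  }
  list(
    layers = best_layers,
    trace = dplyr::bind_rows(trace),
    best_metric = best_metric
  )
}

# ---- autoencoder ------------------------------------------------------

#' Pre-train an autoencoder on a standardized descriptor table
#'
#' Trains a network to reconstruct its own input under mean squared
#' error, to capture the intrinsic low-dimensional relationships among
#' descriptors. With a single entry in `hidden_dims` this is a plain
#' one-hidden-layer autoencoder; with several, autoencoders are stacked
#' greedily: each layer is trained to reconstruct the codes produced by
#' the already-trained layers below it. The resulting encoder weights
#' serve to initialize a classifier of the same architecture via
#' [transfer_weights()].
#'
#' @param data A standardized descriptor table (see [zscore_apply()]);
#'   `label` is ignored here.
#' @param config A [training_config()].
#' @return A `dl_autoencoder` object holding encoder and decoder layers,
#'   per-layer training traces, and the configuration.
#' @export
train_autoencoder <- function(data, config = training_config()) {
  X <- .unnamed_features(data)
  if (!all(is.finite(X))) abort("descriptor matrix contains non-finite values")
  cfg <- config
  .with_seed(cfg$seed, {
    encoders <- list()
    decoders <- list()
    traces <- list()
    code <- X
    in_dim <- ncol(X)
    for (h in cfg$hidden_dims) {
      layers <- list(
        .new_layer(ncol(code), h, cfg$activation, cfg$init_stddev),
        .new_layer(h, ncol(code), "linear", cfg$init_stddev)
      )
      fit <- .nn_train(layers, code, code, "mse", cfg)
      encoders[[length(encoders) + 1L]] <- fit$layers[[1L]]
      decoders[[length(decoders) + 1L]] <- fit$layers[[2L]]
      traces[[length(traces) + 1L]] <- fit$trace
      code <- .nn_forward(fit$layers[1L], code)$a[[2L]]
    }
    structure(
      list(
        encoders = encoders, decoders = decoders, traces = traces,
        config = cfg, input_dim = in_dim,
        feature_names = feature_names(data)
      ),
      class = "dl_autoencoder"
    )
  })
}

#' Reconstruction error of a trained autoencoder
#'
#' Encodes the data through every encoder layer and decodes back down
#' the stack; returns the mean squared error over all entries.
#'
#' @param ae A `dl_autoencoder`.
#' @param data A descriptor table on the scale the autoencoder was
#'   trained on.
#' @return Mean squared reconstruction error.
#' @export
reconstruction_mse <- function(ae, data) {
  X <- .unnamed_features(data)
  code <- X
  for (enc in ae$encoders) code <- .nn_forward(list(enc), code)$a[[2L]]
  recon <- code
  for (dec in rev(ae$decoders)) recon <- .nn_forward(list(dec), recon)$a[[2L]]
  mean((recon - X)^2)
}

#' Initialize a classifier from a pre-trained autoencoder
#'
#' Copies the autoencoder's encoder layers verbatim into the hidden
#' layers of a fully connected classifier of the same architecture, and
#' attaches a freshly initialized single-unit sigmoid output layer. The
#' decoder is discarded.
#'
#' @param ae A `dl_autoencoder` from [train_autoencoder()].
#' @param config A [training_config()]; its `seed` controls only the new
#'   output layer, so two transfers from the same autoencoder with
#'   different seeds share identical hidden layers.
#' @return An untrained `dl_classifier`.
#' @export
transfer_weights <- function(ae, config = ae$config) {
  if (!inherits(ae, "dl_autoencoder")) abort("`ae` must be a dl_autoencoder")
  hidden <- lapply(ae$encoders, identity)
  if (length(hidden) != length(config$hidden_dims) ||
      !all(vapply(hidden, function(l) ncol(l$W), 0L) == config$hidden_dims)) {
    abort("autoencoder architecture does not match `config$hidden_dims`")
  }
  last_dim <- ncol(hidden[[length(hidden)]]$W)
  out_layer <- list(
    W = init_truncated_normal(c(last_dim, 1L), config$init_stddev,
                              seed = config$seed),
    b = 0,
    activation = "sigmoid"
  )
  structure(
    list(
      layers = c(hidden, list(out_layer)),
      config = config,
      input_dim = ae$input_dim,
      feature_names = ae$feature_names,
      pretrained = TRUE,
      trained = FALSE,
      trace = NULL
    ),
    class = "dl_classifier"
  )
}

# ---- classifier -------------------------------------------------------

.fresh_classifier <- function(input_dim, cfg, feature_names = NULL) {
  dims <- c(input_dim, cfg$hidden_dims)
  layers <- vector("list", length(cfg$hidden_dims) + 1L)
  for (l in seq_along(cfg$hidden_dims)) {
    layers[[l]] <- .new_layer(dims[l], dims[l + 1L], cfg$activation,
                              cfg$init_stddev)
  }
  layers[[length(layers)]] <- .new_layer(dims[length(dims)], 1L, "sigmoid",
                                         cfg$init_stddev)
  structure(
    list(layers = layers, config = cfg, input_dim = input_dim,
         feature_names = feature_names, pretrained = FALSE,
         trained = FALSE, trace = NULL),
    class = "dl_classifier"
  )
}

#' Train (fine-tune) the drug-likeness classifier
#'
#' Minimizes the class-weighted binary cross-entropy ([weighted_bce()],
#' batch-mean form) plus the L2 weight penalty by mini-batch gradient
#' descent, with dropout on hidden-layer outputs. When held-out data is
#' supplied, training stops early once held-out classification accuracy
#' has not improved for `early_stop_patience` epochs and the best-ACC
#' weights are restored; otherwise the training loss is monitored.
#'
#' @param data A balanced, standardized descriptor table with a `label`
#'   column.
#' @param config A [training_config()]; ignored when `init` carries one.
#' @param init Optional initial network: a `dl_classifier` from
#'   [transfer_weights()] (autoencoder pre-training) or a previous fit.
#'   `NULL` initializes all layers randomly.
#' @param eval_data Optional held-out descriptor table (with `label`)
#'   used for early stopping.
#' @return A trained `dl_classifier` with a per-epoch `trace` tibble
#'   (`epoch`, `loss`, `monitored`).
#' @export
train_classifier <- function(data, config = training_config(), init = NULL,
                             eval_data = NULL) {
  y <- .check_labels(data$label)
  X <- .unnamed_features(data)
  if (!all(is.finite(X))) abort("descriptor matrix contains non-finite values")
  model <- if (is.null(init)) {
    .fresh_classifier(ncol(X), config, feature_names(data))
  } else {
    if (!inherits(init, "dl_classifier")) {
      abort("`init` must be a dl_classifier")
    }
    init$config <- config
    init
  }
  if (ncol(X) != model$input_dim) {
    abort("descriptor count does not match the network input dimension")
  }
  monitor <- NULL
  maximize <- FALSE
  if (!is.null(eval_data)) {
    y_eval <- .check_labels(eval_data$label)
    X_eval <- .unnamed_features(eval_data)
    monitor <- function(layers) {
      p <- as.numeric(.nn_forward(layers, X_eval)$a[[length(layers) + 1L]])
      mean((p >= 0.5) == (y_eval == 1L))
    }
    maximize <- TRUE
  }
  fit <- .with_seed(config$seed,
                    .nn_train(model$layers, X, y, "wbce", config,
                              monitor_fun = monitor, maximize = maximize))
  model$layers <- fit$layers
  model$trace <- fit$trace
  model$best_metric <- fit$best_metric
  model$trained <- TRUE
  model
}

#' Predict drug-likeness probabilities
#'
#' Deterministic forward pass with dropout disabled; repeated calls give
#' bit-identical results. Rows must be standardized with the statistics
#' fitted on the network's training split.
#'
#' @param object A trained `dl_classifier`.
#' @param new_data A descriptor table with the same descriptor columns.
#' @param threshold Decision threshold for the hard class call.
#' @param ... Unused.
#' @return A tibble with `id` (when present), the positive-class
#'   probability `.prob`, and the thresholded call `.class`.
#' @export
predict.dl_classifier <- function(object, new_data, threshold = 0.5, ...) {
  X <- .unnamed_features(new_data)
  if (ncol(X) != object$input_dim) {
    abort("descriptor count does not match the network input dimension")
  }
  p <- as.numeric(.nn_forward(object$layers, X)$a[[length(object$layers) + 1L]])
  out <- tibble(.prob = p, .class = as.integer(p >= threshold))
  if ("id" %in% names(new_data)) {
    out <- dplyr::bind_cols(tibble(id = new_data$id), out)
  }
  out
}

#' Evaluate a classifier on a labeled descriptor table
#'
#' @param model A trained `dl_classifier`.
#' @param data A standardized descriptor table with `label`.
#' @param threshold Decision threshold.
#' @return A one-row `eval_report` tibble (see [evaluate_predictions()]).
#' @export
evaluate_model <- function(model, data, threshold = 0.5) {
  p <- predict(model, data)$.prob
  evaluate_predictions(data$label, p, threshold)
}

# ---- gradient access (used by verification tests) --------------------

#' Loss and analytic gradients of the classifier objective
#'
#' Evaluates the batch-mean weighted cross-entropy plus L2 penalty and
#' its exact gradients with respect to every weight and bias, with
#' dropout disabled. Exposed so the backpropagation implementation can
#' be checked against finite differences.
#'
#' @param model A `dl_classifier`.
#' @param data Descriptor table with `label`.
#' @return List with `loss` and `grads` (per layer: `W`, `b`).
#' @export
classifier_gradients <- function(model, data) {
  y <- .check_labels(data$label)
  X <- .unnamed_features(data)
  .nn_loss_grad(model$layers, X, y, "wbce", model$config$pos_weight,
                model$config$l2)
}

#' Classifier objective value alone
#'
#' @inheritParams classifier_gradients
#' @param layers Optional replacement layer list (used when probing the
#'   loss surface parameter by parameter).
#' @return The scalar objective.
#' @export
classifier_loss <- function(model, data, layers = NULL) {
  y <- .check_labels(data$label)
  X <- .unnamed_features(data)
  .nn_loss_grad(if (is.null(layers)) model$layers else layers, X, y,
                "wbce", model$config$pos_weight, model$config$l2,
                want_grad = FALSE)$loss
}

# ---- serialization ----------------------------------------------------

#' Save a network to a JSON container
#'
#' Layer weights are written with 17 significant digits, enough to
#' round-trip IEEE doubles exactly: a reloaded network predicts
#' bit-identically.
#'
#' @param x A `dl_classifier` or `dl_autoencoder`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path) {
  # weights go out flattened column-major with explicit dims, so the
  # reload never depends on JSON array-shape simplification heuristics
  ser_layers <- function(layers) lapply(layers, function(ly) list(
    dim = dim(ly$W), W = as.numeric(ly$W), b = as.numeric(ly$b),
    activation = ly$activation
  ))
  obj <- if (inherits(x, "dl_autoencoder")) {
    list(role = "autoencoder", encoders = ser_layers(x$encoders),
         decoders = ser_layers(x$decoders), input_dim = x$input_dim,
         feature_names = x$feature_names, config = unclass(x$config))
  } else if (inherits(x, "dl_classifier")) {
    list(role = "classifier", layers = ser_layers(x$layers),
         input_dim = x$input_dim, feature_names = x$feature_names,
         pretrained = x$pretrained, trained = x$trained,
         config = unclass(x$config))
  } else {
    abort("`x` must be a dl_classifier or dl_autoencoder")
  }
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a network saved by [write_network()]
#'
#' @param path Path to the JSON container.
#' @return A `dl_classifier` or `dl_autoencoder`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  obj <- jsonlite::fromJSON(readLines(path), simplifyDataFrame = FALSE,
                            simplifyMatrix = TRUE)
  de_layers <- function(ls) lapply(ls, function(ly) list(
    W = matrix(as.numeric(ly$W), ly$dim[1L], ly$dim[2L]),
    b = as.numeric(ly$b),
    activation = ly$activation
  ))
  cfg <- structure(obj$config, class = "training_config")
  cfg$hidden_dims <- as.integer(cfg$hidden_dims)
  if (identical(obj$role, "autoencoder")) {
    structure(
      list(encoders = de_layers(obj$encoders),
           decoders = de_layers(obj$decoders),
           traces = NULL, config = cfg, input_dim = obj$input_dim,
           feature_names = obj$feature_names),
      class = "dl_autoencoder"
    )
  } else {
    structure(
      list(layers = de_layers(obj$layers), config = cfg,
           input_dim = obj$input_dim, feature_names = obj$feature_names,
           pretrained = isTRUE(obj$pretrained),
           trained = isTRUE(obj$trained), trace = NULL),
      class = "dl_classifier"
    )
  }
}

#' Exhaustive grid of training configurations
#'
#' A plain helper that crosses the supplied hyperparameter values into a
#' list of [training_config()] objects, for simple exhaustive searches.
#'
#' @param ... Named vectors/lists of `training_config()` argument values.
#' @return A list of `training_config` objects.
#' @export
config_grid <- function(...) {
  grid <- expand.grid(..., stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  purrr::pmap(grid, function(...) do.call(training_config, list(...)))
}

#' @export
print.dl_classifier <- function(x, ...) {
  dims <- c(x$input_dim, vapply(x$layers, function(l) ncol(l$W), 0L))
  cat("<dl_classifier> ", paste(dims, collapse = " -> "),
      if (x$pretrained) " (AE-pretrained)" else "",
      if (x$trained) " [trained]" else " [untrained]", "\n", sep = "")
  invisible(x)
}

#' @export
print.dl_autoencoder <- function(x, ...) {
  dims <- c(x$input_dim, vapply(x$encoders, function(l) ncol(l$W), 0L))
  cat("<dl_autoencoder> encoder ", paste(dims, collapse = " -> "), "\n",
      sep = "")
  invisible(x)
}
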