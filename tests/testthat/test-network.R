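std_table <- function(n, p, seed = 1, ...) {
  args <- utils::modifyList(
    list(n_pos = n / 2, n_neg = n / 2, n_features = p,
         latent_dim = max(2, p %/% 5), seed = seed),
    list(...))
  d <- do.call(simulate_descriptors, args)
  zscore_apply(d, zscore_fit(d))
}

test_that("truncated-normal draws respect bound, mean and determinism", {
  w <- init_truncated_normal(c(200, 50), stddev = 0.1, seed = 3)
  expect_equal(dim(w), c(200, 50))
  expect_true(all(abs(w) <= 0.2))
  big <- init_truncated_normal(1e5, stddev = 0.05, seed = 4)
  expect_lt(abs(mean(big)), 3 * 0.05 / sqrt(1e5))
  expect_identical(init_truncated_normal(c(10, 10), seed = 9),
                   init_truncated_normal(c(10, 10), seed = 9))
})

test_that("weighted loss halves the plain cross-entropy at w = 1/2", {
  set.seed(31)
  for (i in 1:10) {
    y <- rbinom(64, 1, 0.5)
    a <- runif(64, 0.01, 0.99)
    plain <- -sum(y * log(a) + (1 - y) * log(1 - a))
    expect_equal(weighted_bce(y, a, 0.5), 0.5 * plain,
                 tolerance = 1e-10)
  }
  expect_equal(weighted_bce(c(1, 0), c(0.9, 0.2), 0.7),
               -(0.7 * log(0.9) + 0.3 * log(0.8)), tolerance = 1e-12)
  expect_equal(weighted_bce(c(1, 0), c(0.9, 0.2), 0.7), 0.1407,
               tolerance = 1e-4)
  # perfect predictions drive the loss to (clipped) zero
  expect_lt(weighted_bce(c(1, 0), c(1, 0), 0.5), 1e-6)
  expect_error(weighted_bce(c(1, 0), c(0.5, 0.5), 1), "pos_weight")
  # the batch-mean variant is the sum divided by n
  y <- c(1, 0, 1); a <- c(0.8, 0.3, 0.6)
  expect_equal(weighted_bce(y, a, 0.6, reduction = "mean"),
               weighted_bce(y, a, 0.6) / 3)
})

test_that("analytic gradients match central finite differences", {
  d <- std_table(6, 10, seed = 41)
  cfg <- training_config(hidden_dims = c(7L, 5L), dropout = 0,
                         l2 = 1e-4, pos_weight = 0.65, seed = 7)
  m <- druglikeness:::.fresh_classifier(10L, cfg)
  an <- classifier_gradients(m, d)
  h <- 1e-5
  worst <- 0
  for (l in seq_along(m$layers)) {
    for (what in c("W", "b")) {
      g <- an$grads[[l]][[what]]
      for (i in seq_along(g)) {
        lp <- m$layers; lm <- m$layers
        lp[[l]][[what]][i] <- lp[[l]][[what]][i] + h
        lm[[l]][[what]][i] <- lm[[l]][[what]][i] - h
        num <- (classifier_loss(m, d, lp) - classifier_loss(m, d, lm)) / (2 * h)
        worst <- max(worst, abs(g[i] - num) / max(abs(num), 1e-6))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("a full-width linear autoencoder reconstructs almost exactly", {
  d <- std_table(60, 8, seed = 51)
  cfg <- training_config(hidden_dims = 8L, activation = "linear",
                         dropout = 0, l2 = 0, max_epochs = 800,
                         early_stop_patience = 800, batch_size = 60,
                         learning_rate = 0.01, seed = 5)
  ae <- train_autoencoder(d, cfg)
  expect_lt(reconstruction_mse(ae, d), 1e-3)
  # loss trace descends overall
  tr <- ae$traces[[1]]
  expect_lte(tr$loss[nrow(tr)], tr$loss[1])
})

test_that("a bottleneck linear autoencoder attains the PCA optimum", {
  d <- std_table(80, 12, seed = 52, noise_sd = 0, latent_dim = 3)
  X <- feature_matrix(d)
  pr <- stats::prcomp(X, center = FALSE)
  pca_mse <- mean((pr$x[, 1:3] %*% t(pr$rotation[, 1:3]) - X)^2)
  cfg <- training_config(hidden_dims = 3L, activation = "linear",
                         dropout = 0, l2 = 0, max_epochs = 400,
                         early_stop_patience = 400, batch_size = 20,
                         learning_rate = 0.01, seed = 6)
  ae <- train_autoencoder(d, cfg)
  # rank-3 data: the optimum is (numerically) zero, and the trained
  # autoencoder lands within a sliver of the total variance above it
  expect_lt(reconstruction_mse(ae, d) - pca_mse, 0.01 * mean(X^2))
})

test_that("weight transfer copies the encoder bit-exactly", {
  d <- std_table(40, 6, seed = 61)
  cfg <- tiny_config(max_epochs = 5L)
  ae <- train_autoencoder(d, cfg)
  clf <- transfer_weights(ae, cfg)
  expect_identical(clf$layers[[1]]$W, ae$encoders[[1]]$W)
  expect_identical(clf$layers[[1]]$b, ae$encoders[[1]]$b)
  expect_equal(dim(clf$layers[[2]]$W), c(8L, 1L))
  expect_equal(clf$layers[[2]]$activation, "sigmoid")
  # a different seed re-draws only the output layer
  cfg2 <- tiny_config(max_epochs = 5L, seed = 99L)
  clf2 <- transfer_weights(ae, cfg2)
  expect_identical(clf2$layers[[1]]$W, clf$layers[[1]]$W)
  expect_false(identical(clf2$layers[[2]]$W, clf$layers[[2]]$W))
})

test_that("the classifier separates a linearly separable toy problem", {
  set.seed(71)
  n <- 60
  d <- tibble::tibble(
    label = rep(c(1L, 0L), each = n / 2),
    x = c(rnorm(n / 2, 2), rnorm(n / 2, -2)) / 2,
    y = c(rnorm(n / 2, 2), rnorm(n / 2, -2)) / 2
  )
  fit <- train_classifier(d, training_config(
    hidden_dims = 4L, dropout = 0, l2 = 0, batch_size = 16,
    max_epochs = 200, early_stop_patience = 200, seed = 2),
    eval_data = d)
  expect_equal(evaluate_model(fit, d)$acc, 1.0)
  expect_lte(max(fit$trace$epoch), 200)
})

test_that("prediction is deterministic, order-equivariant and calibrated at zero", {
  d <- std_table(30, 5, seed = 81)
  fit <- train_classifier(d, tiny_config(max_epochs = 3L))
  p1 <- predict(fit, d)
  p2 <- predict(fit, d)
  expect_identical(p1, p2)   # dropout is off at inference
  perm <- sample.int(nrow(d))
  expect_equal(predict(fit, d[perm, ])$.prob, p1$.prob[perm])
  # all-zero weights give sigmoid(0) = 1/2 everywhere
  zero <- fit
  zero$layers <- lapply(zero$layers, function(l) {
    l$W[] <- 0; l$b[] <- 0; l
  })
  expect_true(all(predict(zero, d)$.prob == 0.5))
})

test_that("networks survive a JSON serialization round trip bit-exactly", {
  d <- std_table(30, 5, seed = 91)
  cfg <- tiny_config(max_epochs = 4L)
  ae <- train_autoencoder(d, cfg)
  clf <- train_classifier(d, cfg, init = transfer_weights(ae, cfg))
  path <- withr::local_tempfile(fileext = ".json")
  write_network(clf, path)
  back <- read_network(path)
  for (l in seq_along(clf$layers)) {
    expect_identical(back$layers[[l]]$W, clf$layers[[l]]$W)
    expect_identical(back$layers[[l]]$b, as.numeric(clf$layers[[l]]$b))
  }
  expect_identical(predict(back, d)$.prob, predict(clf, d)$.prob)
  # autoencoders round-trip too
  write_network(ae, path)
  ae2 <- read_network(path)
  expect_identical(ae2$encoders[[1]]$W, ae$encoders[[1]]$W)
})

test_that("raising the positive weight raises sensitivity on imbalanced data", {
  se_at <- function(w, seed) {
    d <- simulate_descriptors(20, 200, n_features = 10, latent_dim = 3,
                              class_shift = 1.2, noise_sd = 0.5,
                              seed = seed)
    ds <- zscore_apply(d, zscore_fit(d))
    cfg <- training_config(hidden_dims = 8L, dropout = 0, l2 = 1e-5,
                           batch_size = 32, max_epochs = 30,
                           early_stop_patience = 30, pos_weight = w,
                           seed = seed)
    fit <- train_classifier(ds, cfg)
    suppressWarnings(evaluate_model(fit, ds)$se)
  }
  seeds <- 1:5
  hi <- vapply(seeds, function(s) se_at(0.9, s), numeric(1))
  lo <- vapply(seeds, function(s) se_at(0.5, s), numeric(1))
  expect_gte(median(hi), median(lo))
})

test_that("one hidden layer is at least as good as two on latent-factor data", {
  accs <- vapply(1:3, function(s) {
    d <- simulate_descriptors(150, 150, n_features = 40, latent_dim = 5,
                              class_shift = 2, noise_sd = 0.5, seed = s)
    plan <- make_split(d$label, seed = s)
    tr <- d[plan$row[plan$role == "train"], ]
    va <- d[plan$row[plan$role == "validation"], ]
    st <- zscore_fit(tr)
    trs <- zscore_apply(tr, st); vas <- zscore_apply(va, st)
    fit1 <- train_classifier(trs, tiny_config(hidden_dims = 16L, seed = s),
                             eval_data = vas)
    fit2 <- train_classifier(trs,
                             tiny_config(hidden_dims = c(16L, 8L), seed = s),
                             eval_data = vas)
    evaluate_model(fit1, vas)$acc - evaluate_model(fit2, vas)$acc
  }, numeric(1))
  expect_gte(median(accs), 0)
})

test_that("configuration validation rejects out-of-range settings", {
  expect_error(training_config(dropout = 1), "dropout")
  expect_error(training_config(pos_weight = 0), "pos_weight")
  expect_error(training_config(pos_weight = 1.2), "pos_weight")
  grid <- config_grid(hidden_dims = c(4L, 8L), pos_weight = c(0.5, 0.7))
  expect_length(grid, 4)
  expect_s3_class(grid[[1]], "training_config")
})
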