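#' Deterministic 9:1 split with stratified cross-validation folds
#'
#' Assigns every row either to the held-out validation set (a 1/10
#' fraction by default) or to one of `fold_count` cross-validation folds
#' within the training portion. Both assignments are stratified by
#' class, so even a 1:59 imbalanced set keeps positives in the
#' validation set and in every fold.
#'
#' @param labels Binary 0/1 class vector, one entry per row.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @param validation_fraction Fraction held out, default 0.1.
#' @param fold_count Number of CV folds within the training rows.
#' @param stratified Stratify by class (default). Unstratified splitting
#'   is plain uniform sampling.
#' @return A `split_plan` tibble with columns `row`, `label`, `role`
#'   (`"train"`/`"validation"`) and `fold` (1..`fold_count`, `NA` for
#'   validation rows). Attributes record the parameters.
#' @export
make_split <- function(labels, seed = NULL, validation_fraction = 0.1,
                       fold_count = 5L, stratified = TRUE) {
  labels <- .check_labels(labels, "labels")
  n <- length(labels)
  if (n < 2L * fold_count) abort("too few rows for the requested folds")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must be in (0, 1)")
  }
  .with_seed(seed, {
    role <- rep("train", n)
    if (stratified) {
      for (cls in unique(labels)) {
        rows <- which(labels == cls)
        n_val <- round(length(rows) * validation_fraction)
        if (n_val == 0L && length(rows) >= 2L) n_val <- 1L
        role[sample(rows, n_val)] <- "validation"
      }
    } else {
      n_val <- round(n * validation_fraction)
      role[sample.int(n, n_val)] <- "validation"
    }
    fold <- rep(NA_integer_, n)
    train_rows <- which(role == "train")
    if (stratified) {
      # deal shuffled rows round-robin, the counter running across
      # classes so overall fold sizes also differ by at most one
      counter <- 0L
      for (cls in unique(labels)) {
        rows <- train_rows[labels[train_rows] == cls]
        rows <- rows[sample.int(length(rows))]
        fold[rows] <- (counter + seq_along(rows) - 1L) %% fold_count + 1L
        counter <- counter + length(rows)
      }
    } else {
      rows <- train_rows[sample.int(length(train_rows))]
      fold[rows] <- (seq_along(rows) - 1L) %% fold_count + 1L
    }
    for (cls in unique(labels)) {
      if (!any(labels == cls & role == "validation")) {
        abort(sprintf("class %d absent from the validation set; increase the fraction", cls))
      }
    }
    structure(
      tibble(row = seq_len(n), label = labels, role = role, fold = fold),
      class = c("split_plan", class(tibble())),
      seed = seed, validation_fraction = validation_fraction,
      fold_count = as.integer(fold_count), stratified = stratified
    )
  })
}

.balance_with <- function(data, method, seed, smote_k) {
  switch(method,
    duplicate = oversample_duplicate(data, seed = seed),
    smote = oversample_smote(data, k = smote_k, seed = seed),
    none = {
      data$.synthetic <- FALSE
      data
    },
    abort(sprintf("unknown balance method '%s'", method))
  )
}

# Standardize train/eval tables on statistics fitted on the training
# rows only, dropping any column that is constant within them.
.fold_standardize <- function(train, others) {
  m <- feature_matrix(train)
  sds <- sqrt(colMeans(sweep(m, 2L, colMeans(m))^2))
  dead <- names(which(sds == 0))
  if (length(dead) > 0L) {
    train <- train[setdiff(names(train), dead)]
    others <- lapply(others, function(d) d[setdiff(names(d), dead)])
  }
  stats <- zscore_fit(train)
  list(
    train = zscore_apply(train, stats),
    others = lapply(others, zscore_apply, stats = stats),
    stats = stats
  )
}

#' Run the full cross-validated training experiment
#'
#' For each cross-validation fold: z-score statistics are fitted on the
#' fold-training rows only; the fold-training rows are balanced
#' (duplication or SMOTE); an autoencoder is pre-trained on them; the
#' classifier is initialized from it and fine-tuned with the weighted
#' loss, stopping early on fold-test accuracy; and the fitted model is
#' evaluated on its fold-test rows and on the untouched validation
#' split. Per-fold reports are averaged into the final judgement.
#'
#' Balancing is applied inside each fold rather than to the whole
#' training set up front, so no synthetic point is interpolated from a
#' fold's own test rows; the historical whole-training-set variant is
#' available via `leaky_balance = TRUE` for fidelity comparisons.
#'
#' @param data A post-processed, labeled descriptor table.
#' @param config A [training_config()].
#' @param balance_method `"smote"`, `"duplicate"`, or `"none"`.
#' @param plan A [make_split()] plan; `NULL` builds one from
#'   `config$seed`.
#' @param smote_k SMOTE neighbor count.
#' @param leaky_balance Balance the full training set before the folds
#'   are cut (the protocol leak described above).
#' @return An `experiment_result` list: `folds` (per-fold `eval_report`
#'   rows on fold-test), `fold_mean` (their arithmetic mean),
#'   `validation` (per-fold reports on the validation split),
#'   `validation_mean`, the `plan`, `config`, `models` (per-fold
#'   classifiers), and `stats` (per-fold standardization).
#' @export
run_experiment <- function(data, config = training_config(),
                           balance_method = c("smote", "duplicate", "none"),
                           plan = NULL, smote_k = 5L,
                           leaky_balance = FALSE) {
  balance_method <- match.arg(balance_method)
  labels <- .check_labels(data$label)
  if (is.null(plan)) plan <- make_split(labels, seed = config$seed)
  if (nrow(plan) != nrow(data)) abort("plan does not match the data rows")
  val_rows <- plan$row[plan$role == "validation"]
  train_plan <- plan[plan$role == "train", ]
  fold_ids <- sort(unique(train_plan$fold))

  pre_balanced <- NULL
  if (leaky_balance) {
    tr_all <- data[train_plan$row, , drop = FALSE]
    tr_all$.fold <- train_plan$fold
    pre_balanced <- .balance_with(tr_all, balance_method, config$seed,
                                  smote_k)
    # synthetic rows inherit no fold; spread them round-robin
    syn <- which(pre_balanced$.synthetic)
    if (length(syn) > 0L) {
      pre_balanced$.fold[syn] <- (seq_along(syn) - 1L) %% length(fold_ids) + 1L
    }
  }

  fold_reports <- list()
  val_reports <- list()
  models <- list()
  fold_stats <- list()
  for (f in fold_ids) {
    test_rows <- train_plan$row[train_plan$fold == f]
    tr_rows <- train_plan$row[train_plan$fold != f]
    if (length(unique(labels[test_rows])) < 2L ||
        length(unique(labels[tr_rows])) < 2L) {
      abort(sprintf("fold %d contains a single class", f))
    }
    if (leaky_balance) {
      fold_train <- pre_balanced[pre_balanced$.fold != f, , drop = FALSE]
      fold_train$.fold <- NULL
    } else {
      fold_train <- data[tr_rows, , drop = FALSE]
    }
    fold_test <- data[test_rows, , drop = FALSE]
    validation <- data[val_rows, , drop = FALSE]

    std <- .fold_standardize(fold_train, list(test = fold_test,
                                              validation = validation))
    fold_train <- std$train
    if (!leaky_balance) {
      fold_train <- .balance_with(fold_train, balance_method,
                                  config$seed + f, smote_k)
    }
    ae <- train_autoencoder(fold_train, config)
    clf <- train_classifier(fold_train, config,
                            init = transfer_weights(ae, config),
                            eval_data = std$others$test)
    fold_reports[[as.character(f)]] <- evaluate_model(clf, std$others$test)
    val_reports[[as.character(f)]] <- evaluate_model(clf,
                                                     std$others$validation)
    models[[as.character(f)]] <- clf
    fold_stats[[as.character(f)]] <- std$stats
  }
  folds <- dplyr::bind_rows(fold_reports, .id = "fold")
  vals <- dplyr::bind_rows(val_reports, .id = "fold")
  structure(
    list(
      folds = folds,
      fold_mean = .mean_report(folds),
      validation = vals,
      validation_mean = .mean_report(vals),
      plan = plan, config = config,
      balance_method = balance_method,
      models = models, stats = fold_stats
    ),
    class = "experiment_result"
  )
}

.mean_report <- function(reports) {
  num <- reports[setdiff(names(reports), "fold")]
  as_tibble(as.list(colMeans(as.matrix(num))))
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", x$balance_method, " balancing, ",
      nrow(x$folds), " folds\n", sep = "")
  cat("fold-test mean:\n")
  print(x$fold_mean[c("acc", "se", "sp", "mcc", "auc")])
  cat("validation mean:\n")
  print(x$validation_mean[c("acc", "se", "sp", "mcc", "auc")])
  invisible(x)
}
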