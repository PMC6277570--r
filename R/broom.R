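#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a trained classifier: one row per layer
#'
#' @param x A `dl_classifier`.
#' @param ... Unused.
#' @return A tibble with `layer`, `input_dim`, `output_dim`,
#'   `activation`, `n_parameters`.
#' @exportS3Method generics::tidy
#' @export
tidy.dl_classifier <- function(x, ...) {
  purrr::imap_dfr(x$layers, function(ly, i) tibble(
    layer = i,
    input_dim = nrow(ly$W),
    output_dim = ncol(ly$W),
    activation = ly$activation,
    n_parameters = length(ly$W) + length(ly$b)
  ))
}

#' One-row summary of a trained classifier
#'
#' @param x A `dl_classifier`.
#' @param ... Unused.
#' @return A tibble with architecture and training summary columns.
#' @exportS3Method generics::glance
#' @export
glance.dl_classifier <- function(x, ...) {
  tibble(
    n_layers = length(x$layers),
    hidden_dims = paste(x$config$hidden_dims, collapse = ","),
    pretrained = x$pretrained,
    trained = x$trained,
    pos_weight = x$config$pos_weight,
    epochs = if (is.null(x$trace)) NA_integer_ else max(x$trace$epoch),
    final_loss = if (is.null(x$trace)) NA_real_ else
      x$trace$loss[nrow(x$trace)],
    best_monitored = x$best_metric %||% NA_real_
  )
}

#' Tidy an autoencoder: one row per encoder layer
#'
#' @param x A `dl_autoencoder`.
#' @param ... Unused.
#' @return A tibble of encoder layer shapes and final training losses.
#' @exportS3Method generics::tidy
#' @export
tidy.dl_autoencoder <- function(x, ...) {
  purrr::imap_dfr(x$encoders, function(ly, i) tibble(
    layer = i,
    input_dim = nrow(ly$W),
    code_dim = ncol(ly$W),
    activation = ly$activation,
    final_loss = if (is.null(x$traces)) NA_real_ else
      x$traces[[i]]$loss[nrow(x$traces[[i]])]
  ))
}

#' Tidy a weight scan (the per-weight metric table)
#'
#' @param x A `weight_scan`.
#' @param ... Unused.
#' @return The scan as a plain tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.weight_scan <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a weight scan
#'
#' @param x A `weight_scan`.
#' @param ... Unused.
#' @return A tibble with the selected weight, the selection rule, and
#'   the SE/SP gap at the nearest grid point.
#' @exportS3Method generics::glance
#' @export
glance.weight_scan <- function(x, ...) {
  sel <- attr(x, "selected_w")
  i <- which.min(abs(x$w - sel))
  tibble(
    selected_w = sel,
    selection_rule = attr(x, "selection_rule"),
    gap_at_selected = abs(x$se[i] - x$sp[i]),
    n_grid = nrow(x)
  )
}

#' Tidy an experiment result: per-fold evaluation rows
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return A tibble of per-fold reports on fold-test and validation
#'   data, distinguished by the `split` column.
#' @exportS3Method generics::tidy
#' @export
tidy.experiment_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$folds, split = "fold_test"),
    dplyr::mutate(x$validation, split = "validation")
  )
}

#' One-row summary of an experiment
#'
#' @param x An `experiment_result`.
#' @param ... Unused.
#' @return A tibble with mean fold-test and validation metrics.
#' @exportS3Method generics::glance
#' @export
glance.experiment_result <- function(x, ...) {
  fm <- x$fold_mean
  vm <- x$validation_mean
  tibble(
    balance_method = x$balance_method,
    n_folds = nrow(x$folds),
    fold_acc = fm$acc, fold_se = fm$se, fold_sp = fm$sp,
    fold_mcc = fm$mcc, fold_auc = fm$auc,
    val_acc = vm$acc, val_se = vm$se, val_sp = vm$sp,
    val_mcc = vm$mcc, val_auc = vm$auc
  )
}
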