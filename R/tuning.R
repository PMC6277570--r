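#' Grid of positive-loss weights
#'
#' The default scan range for the positive-sample loss weight: 0.5 to
#' 1.0 divided into 20 intervals, i.e. 21 grid points 0.025 apart. The
#' upper endpoint is nudged just inside 1 since the weighted loss is
#' only defined for `w` strictly inside (0, 1).
#'
#' @param from,to Range endpoints.
#' @param intervals Number of intervals between them.
#' @return A strictly increasing numeric vector of `intervals + 1`
#'   weights.
#' @export
weight_grid <- function(from = 0.5, to = 1, intervals = 20L) {
  stopifnot(intervals >= 1L, from < to)
  g <- seq(from, to, length.out = intervals + 1L)
  g[g >= 1] <- 1 - 1e-6
  g[g <= 0] <- 1e-6
  g
}

#' Scan the positive-loss weight and record validation metrics
#'
#' Trains one classifier per grid value of the positive-sample loss
#' weight `w` and evaluates each on the validation table, recording
#' ACC, SE, SP, MCC and AUC per weight. All runs share the same seed
#' and — when `ae` is supplied (recommended) — the same autoencoder
#' pre-trained initialization, so the scan isolates the effect of `w`.
#'
#' Both tables must already be standardized with statistics fitted on
#' the training rows; `train` should already be balanced.
#'
#' @param train Balanced, standardized training table with `label`.
#' @param validation Standardized validation table with `label`.
#' @param config A [training_config()]; its `pos_weight` is overridden
#'   by each grid value in turn.
#' @param grid Weight grid, default [weight_grid()].
#' @param ae Optional `dl_autoencoder` to initialize every run from.
#'   `NULL` pre-trains one internally on `train`.
#' @param refine If `TRUE`, after the first pass a second scan at one
#'   fifth of the grid step is run around the selected weight.
#' @return A `weight_scan` object: a tibble with one row per weight
#'   (`w`, `acc`, `se`, `sp`, `mcc`, `auc`) plus attributes
#'   `selected_w` and `selection_rule` filled in by [select_weight()].
#' @export
scan_weights <- function(train, validation, config = training_config(),
                         grid = weight_grid(), ae = NULL, refine = FALSE) {
  if (any(grid <= 0 | grid >= 1)) {
    abort("weight grid must lie strictly inside (0, 1)")
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("weight grid must be strictly increasing")
  }
  if (is.null(ae)) ae <- train_autoencoder(train, config)
  one <- function(w) {
    cfg_w <- config
    cfg_w$pos_weight <- w
    init <- transfer_weights(ae, cfg_w)
    fit <- train_classifier(train, cfg_w, init = init,
                            eval_data = validation)
    rep <- evaluate_model(fit, validation)
    dplyr::bind_cols(tibble(w = w), rep[c("acc", "se", "sp", "mcc", "auc")])
  }
  res <- purrr::map_dfr(grid, one)
  scan <- structure(res, class = c("weight_scan", class(tibble())))
  scan <- .attach_selection(scan)
  if (refine) {
    step <- (grid[2L] - grid[1L]) / 5
    centre <- attr(scan, "selected_w")
    sub <- seq(centre - 2 * step, centre + 2 * step, by = step)
    sub <- sub[sub > 0 & sub < 1 & !(sub %in% res$w)]
    if (length(sub) > 0L) {
      res2 <- purrr::map_dfr(sort(sub), one)
      res <- dplyr::arrange(dplyr::bind_rows(res, res2), .data$w)
      scan <- structure(res, class = c("weight_scan", class(tibble())))
      scan <- .attach_selection(scan)
    }
  }
  scan
}

.attach_selection <- function(scan) {
  sel <- select_weight(scan)
  attr(scan, "selected_w") <- as.numeric(sel)
  attr(scan, "selection_rule") <- attr(sel, "rule")
  scan
}

#' Select the weight where sensitivity and specificity cross
#'
#' The balanced operating point is the weight at which the SE and SP
#' curves intersect. If the sign of `SE - SP` changes between two
#' adjacent grid points, the crossing is located by linear
#' interpolation; when the curves never cross on the grid, the grid
#' point with the smallest `|SE - SP|` is returned instead (ties to the
#' smaller weight). The rule used is recorded in the scan's
#' `selection_rule` attribute.
#'
#' @param scan A `weight_scan` from [scan_weights()], or any tibble with
#'   columns `w`, `se`, `sp`.
#' @return The selected weight (also stored on `scan` by
#'   [scan_weights()]).
#' @export
select_weight <- function(scan) {
  if (nrow(scan) == 0L) abort("empty weight scan")
  d <- scan$se - scan$sp
  if (anyNA(d)) abort("scan contains undefined SE or SP")
  if (nrow(scan) == 1L) {
    return(structure(scan$w[1L], rule = "single_point"))
  }
  exact <- which(d == 0)
  if (length(exact) > 0L) {
    sel <- scan$w[exact[1L]]
    rule <- "crossing_interpolated"
  } else {
    sgn <- sign(d)
    flips <- which(sgn[-1L] != sgn[-length(sgn)])
    if (length(flips) > 0L) {
      i <- flips[1L]
      sel <- scan$w[i] + d[i] * (scan$w[i + 1L] - scan$w[i]) /
        (d[i] - d[i + 1L])
      rule <- "crossing_interpolated"
    } else {
      sel <- scan$w[which.min(abs(d))]
      rule <- "min_abs_gap"
    }
  }
  structure(sel, rule = rule)
}
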