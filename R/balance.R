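.balance_setup <- function(data, seed) {
  labels <- .check_labels(data$label)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    abort("balancing requires both classes to be present")
  }
  minority <- if (n_pos <= n_neg) 1L else 0L
  list(labels = labels, minority = minority,
       n_needed = abs(n_pos - n_neg),
       min_idx = which(labels == minority))
}

.finish_balance <- function(data, new_rows, method, seed) {
  data$.synthetic <- FALSE
  if (!is.null(new_rows) && nrow(new_rows) > 0L) {
    new_rows$.synthetic <- TRUE
    out <- dplyr::bind_rows(data, new_rows)
  } else {
    out <- data
  }
  attr(out, "balance") <- list(method = method, seed = seed,
                               n_synthetic = sum(out$.synthetic))
  out
}

#' Balance classes by duplicating minority rows
#'
#' Randomly re-samples minority-class rows with replacement and appends
#' exact copies until the positive and negative counts are equal (the
#' "copy the minority class" scheme). Original rows come first and are
#' untouched; appended rows are flagged in a `.synthetic` column.
#'
#' @param data A labeled descriptor table.
#' @param seed Integer seed making the resampling reproducible.
#' @return The balanced table with a logical `.synthetic` column; the
#'   `"balance"` attribute records method, seed and the number of rows
#'   appended.
#' @export
oversample_duplicate <- function(data, seed = NULL) {
  st <- .balance_setup(data, seed)
  if (st$n_needed == 0L) return(.finish_balance(data, NULL, "duplicate", seed))
  picks <- .with_seed(seed,
    sample(st$min_idx, st$n_needed, replace = TRUE))
  new_rows <- data[picks, , drop = FALSE]
  # duplicated ids are suffixed so row ids stay unique
  if ("id" %in% names(new_rows)) {
    new_rows$id <- sprintf("%s_dup%04d", new_rows$id, seq_len(nrow(new_rows)))
  }
  .finish_balance(data, new_rows, "duplicate", seed)
}

#' Balance classes with SMOTE
#'
#' Synthetic Minority Over-sampling TEchnique: each synthetic row is
#' `x_i + u * (x_nn - x_i)` where `x_i` is a randomly chosen minority
#' row, `x_nn` one of its `k` nearest minority neighbors (Euclidean
#' distance, neighbor search within the minority class only), and
#' `u ~ Uniform(0, 1)`. Rows are appended until the class counts are
#' equal, so every synthetic point lies on a segment between two
#' minority points — inside the minority convex hull.
#'
#' @param data A labeled descriptor table with a minority class of at
#'   least two rows.
#' @param k Number of nearest neighbors considered; silently reduced to
#'   `minority size - 1` for tiny classes. Distance ties are broken by
#'   row index for determinism.
#' @param seed Integer seed.
#' @return The balanced table, as in [oversample_duplicate()]; the
#'   `"balance"` attribute additionally records `k` and, for each
#'   synthetic row, the indices of its parent pair.
#' @export
oversample_smote <- function(data, k = 5L, seed = NULL) {
  if (k < 1L) abort("`k` must be at least 1")
  st <- .balance_setup(data, seed)
  n_min <- length(st$min_idx)
  if (st$n_needed == 0L) {
    out <- .finish_balance(data, NULL, "smote", seed)
    attr(out, "balance")$k <- as.integer(k)
    return(out)
  }
  if (n_min < 2L) {
    abort(paste("SMOTE needs a minority class of at least 2 rows;",
                "use oversample_duplicate() instead"))
  }
  k_eff <- min(as.integer(k), n_min - 1L)
  M <- feature_matrix(data)[st$min_idx, , drop = FALSE]
  if (!all(is.finite(M))) abort("descriptor matrix contains non-finite values")
  # pairwise distances within the minority class; ties broken by index
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k_eff)]))

  synth <- .with_seed(seed, {
    base <- sample.int(n_min, st$n_needed, replace = TRUE)
    pick <- sample.int(k_eff, st$n_needed, replace = TRUE)
    u <- stats::runif(st$n_needed)
    nbr <- nn[cbind(base, pick)]
    x <- M[base, , drop = FALSE]
    x + u * (M[nbr, , drop = FALSE] - x)
  })
  # rebuild the appended rows from template minority rows
  base_rows <- data[st$min_idx, , drop = FALSE]
  tmpl <- base_rows[rep(1L, st$n_needed), , drop = FALSE]
  tmpl[feature_names(data)] <- as_tibble(synth)
  tmpl$label <- st$minority
  if ("id" %in% names(tmpl)) {
    tmpl$id <- sprintf("smote%06d", seq_len(st$n_needed))
  }
  out <- .finish_balance(data, tmpl, "smote", seed)
  attr(out, "balance")$k <- k_eff
  out
}
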