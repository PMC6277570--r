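#' Remove molecules whose descriptor vector contains an error value
#'
#' Descriptor calculators emit `N/A` or infinite values for molecules
#' they cannot handle; any row containing a missing or non-finite
#' descriptor entry is dropped. The column set is unchanged.
#'
#' @param data A descriptor table.
#' @return The table without the affected rows. The attribute
#'   `"removed_row_ids"` lists the ids (or row indices, when there is no
#'   `id` column) of the rows removed.
#' @export
drop_error_rows <- function(data) {
  m <- feature_matrix(data)
  bad <- !matrixStats_row_all_finite(m)
  if (all(bad)) abort("every row contains an error value; nothing left")
  out <- data[!bad, , drop = FALSE]
  removed <- if ("id" %in% names(data)) data$id[bad] else which(bad)
  attr(out, "removed_row_ids") <- removed
  out
}

# rowwise all-finite without building an n x p logical intermediate twice
matrixStats_row_all_finite <- function(m) {
  ok <- is.finite(m)
  rowSums(ok) == ncol(m)
}

#' Remove descriptors that are constant across all molecules
#'
#' A descriptor taking the same value for every molecule carries no
#' information and breaks z-score standardization; such columns are
#' removed. Equality is exact, matching the convention that a column
#' differing in even one entry is kept.
#'
#' @param data A descriptor table with at least one row.
#' @return The table without constant columns; the attribute
#'   `"removed_col_names"` lists the dropped descriptor names.
#' @export
drop_constant_columns <- function(data) {
  if (nrow(data) == 0L) abort("descriptor table has no rows")
  cols <- feature_names(data)
  m <- feature_matrix(data)
  is_const <- apply(m, 2L, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || all(x == x[1L])
  })
  if (all(is_const)) abort("every descriptor column is constant; nothing left")
  out <- data[c(intersect(names(data), .reserved_cols), cols[!is_const])]
  # preserve original column order
  out <- out[intersect(names(data), names(out))]
  attr(out, "removed_col_names") <- cols[is_const]
  out
}

#' Fit per-descriptor z-score statistics on a designated row subset
#'
#' Means and standard deviations are computed on the fitting subset only
#' (typically the training split), so that standardizing validation data
#' with the returned statistics leaks no validation information. The
#' standard deviation uses the population convention (divide by n).
#'
#' @param data A descriptor table.
#' @param fit_rows Integer or logical index of the rows to fit on;
#'   defaults to all rows.
#' @return A `column_stats` tibble with columns `column`, `mean`, `sd`.
#' @export
zscore_fit <- function(data, fit_rows = NULL) {
  m <- feature_matrix(data)
  if (!is.null(fit_rows)) m <- m[fit_rows, , drop = FALSE]
  if (nrow(m) < 2L) {
    abort("z-score fitting needs at least two rows (sd is degenerate)")
  }
  if (!all(is.finite(m))) {
    abort("fit rows contain non-finite values; run drop_error_rows() first")
  }
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  if (any(sd_pop == 0)) {
    abort(paste0(
      "zero standard deviation on fit rows for: ",
      paste(colnames(m)[sd_pop == 0], collapse = ", "),
      "; run drop_constant_columns() first"
    ))
  }
  structure(
    tibble(column = colnames(m), mean = unname(mu), sd = unname(sd_pop)),
    class = c("column_stats", "tbl_df", "tbl", "data.frame")
  )
}

#' Standardize a descriptor table with previously fitted statistics
#'
#' Applies `(x - mean) / sd` per column, with statistics fitted by
#' [zscore_fit()] on the training rows. Can be applied to any row set
#' (training or held-out) sharing the same descriptor columns.
#'
#' @param data A descriptor table.
#' @param stats A `column_stats` object from [zscore_fit()].
#' @return The standardized table.
#' @export
zscore_apply <- function(data, stats) {
  cols <- feature_names(data)
  if (!identical(sort(cols), sort(stats$column))) {
    abort("descriptor columns do not match the fitted statistics")
  }
  idx <- match(cols, stats$column)
  m <- feature_matrix(data)
  m <- sweep(m, 2L, stats$mean[idx], "-")
  m <- sweep(m, 2L, stats$sd[idx], "/")
  data[cols] <- as_tibble(m)
  data
}

#' Invert a z-score standardization
#'
#' @inheritParams zscore_apply
#' @return The table on the original descriptor scale.
#' @export
zscore_invert <- function(data, stats) {
  cols <- feature_names(data)
  if (!identical(sort(cols), sort(stats$column))) {
    abort("descriptor columns do not match the fitted statistics")
  }
  idx <- match(cols, stats$column)
  m <- feature_matrix(data)
  m <- sweep(m, 2L, stats$sd[idx], "*")
  m <- sweep(m, 2L, stats$mean[idx], "+")
  data[cols] <- as_tibble(m)
  data
}

#' Read a descriptor matrix from delimited text
#'
#' Expects a header row of descriptor names with the first column
#' holding the molecule identifier. Labels may come either as a `label`
#' column or from a separate two-column (id, label) file. The error
#' tokens `NA`, `N/A`, `NaN`, empty fields and `Inf`/`-Inf` are read as
#' missing/non-finite values and left for [drop_error_rows()] to handle.
#'
#' @param path Path to the matrix file (CSV, or TSV when the file name
#'   ends in `.tsv`).
#' @param label_path Optional path to a delimited id,label file.
#' @return A descriptor table.
#' @export
read_descriptor_matrix <- function(path, label_path = NULL) {
  if (!file.exists(path)) abort(sprintf("matrix file not found: %s", path))
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  na_tokens <- c("", "NA", "N/A", "NaN", "n/a")
  d <- reader(path, na = na_tokens, show_col_types = FALSE,
              progress = FALSE)
  names(d)[1L] <- "id"
  d$id <- as.character(d$id)
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) {
      abort(sprintf("label file not found: %s", label_path))
    }
    lreader <- if (grepl("\\.tsv$", label_path)) readr::read_tsv else readr::read_csv
    lab <- lreader(label_path, na = na_tokens, show_col_types = FALSE,
                   progress = FALSE)
    names(lab)[1:2] <- c("id", "label")
    lab$id <- as.character(lab$id)
    d <- dplyr::left_join(d, lab[c("id", "label")], by = "id")
  }
  if ("label" %in% names(d)) d$label <- .check_labels(d$label)
  d <- d[c(intersect(c("id", "label"), names(d)),
           setdiff(names(d), c("id", "label")))]
  as_tibble(d)
}

#' Write a descriptor table to delimited text
#'
#' @param data A descriptor table.
#' @param path Output path; `.tsv` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_descriptor_matrix <- function(data, path) {
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  writer(data, path, progress = FALSE)
  invisible(path)
}
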