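#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Column names that are never treated as descriptors.
.reserved_cols <- c("id", "label", ".synthetic", ".fold")

#' Names of the descriptor (feature) columns of a descriptor table
#'
#' A descriptor table is an ordinary tibble with one row per molecule:
#' an `id` column, an optional binary `label` column (1 = positive /
#' drug-like, 0 = negative), an optional `.synthetic` marker added by the
#' balancing step, and any number of numeric descriptor columns.
#'
#' @param data A descriptor table.
#' @return Character vector of descriptor column names, in table order.
#' @export
feature_names <- function(data) {
  setdiff(names(data), .reserved_cols)
}

#' Extract the numeric descriptor matrix from a descriptor table
#'
#' @param data A descriptor table (see [feature_names()]).
#' @return A numeric matrix, rows in table order, `id`s as row names when
#'   present.
#' @export
feature_matrix <- function(data) {
  cols <- feature_names(data)
  if (length(cols) == 0L) {
    abort("descriptor table has no descriptor columns")
  }
  m <- as.matrix(data[cols])
  if (!is.numeric(m)) {
    abort("descriptor columns must all be numeric")
  }
  if ("id" %in% names(data)) rownames(m) <- as.character(data$id)
  m
}

.check_labels <- function(labels, arg = "label") {
  if (is.null(labels)) abort(sprintf("column `%s` is required", arg))
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    abort(sprintf("`%s` must be binary 0/1 with no missing values", arg))
  }
  as.integer(labels)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# NULL leaves the caller's RNG stream untouched.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
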