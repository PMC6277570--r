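strip_meta <- function(d) {
  attr(d, "removed_row_ids") <- NULL
  attr(d, "removed_col_names") <- NULL
  as.data.frame(d)
}

make_table <- function(m, labels = NULL) {
  d <- dplyr::bind_cols(
    tibble::tibble(id = sprintf("m%02d", seq_len(nrow(m)))),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
  if (!is.null(labels)) d <- dplyr::mutate(d, label = labels, .after = "id")
  d
}

test_that("rows containing error values are removed, columns untouched", {
  m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("d", 1:4)))
  m[2, 3] <- NA
  m[5, 4] <- Inf
  d <- make_table(m)
  out <- drop_error_rows(d)
  expect_equal(out$id, d$id[c(1, 3, 4)])
  expect_equal(attr(out, "removed_row_ids"), d$id[c(2, 5)])
  expect_equal(feature_names(out), feature_names(d))
  # identity on clean data, and idempotent
  clean <- drop_error_rows(out)
  expect_equal(strip_meta(clean), strip_meta(out))
  expect_error(drop_error_rows(make_table(matrix(NA_real_, 2, 2,
    dimnames = list(NULL, c("a", "b"))))), "nothing left")
})

test_that("constant columns are removed exactly, near-constant kept", {
  m <- cbind(x = rnorm(6), const = rep(7, 6), almost = c(rep(1, 5), 1.000001))
  d <- make_table(m)
  out <- drop_constant_columns(d)
  expect_equal(feature_names(out), c("x", "almost"))
  expect_equal(attr(out, "removed_col_names"), "const")
  expect_equal(nrow(out), nrow(d))
  # idempotence and identity when nothing is constant
  again <- drop_constant_columns(out)
  expect_equal(strip_meta(again), strip_meta(out))
})

test_that("column removal decisions are invariant under row permutation", {
  set.seed(11)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("d", 1:6)))
  m[, 2] <- 3
  m[, 5] <- -1
  d <- make_table(m)
  for (i in 1:5) {
    perm <- d[sample.int(nrow(d)), ]
    expect_equal(attr(drop_constant_columns(perm), "removed_col_names"),
                 attr(drop_constant_columns(d), "removed_col_names"))
  }
})

test_that("z-score statistics match the population-sd hand computation", {
  d <- make_table(cbind(a = c(1, 2, 3, 99), b = c(0, 10, 20, -99)))
  st <- zscore_fit(d, fit_rows = 1:3)
  expect_equal(st$mean[st$column == "a"], 2)
  expect_equal(st$sd[st$column == "a"], sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$sd[st$column == "a"], 0.8165, tolerance = 1e-4)
  # statistics ignore rows outside the fitting subset
  d2 <- d
  d2[4, c("a", "b")] <- list(1e6, -1e6)
  expect_equal(zscore_fit(d2, 1:3), st)
  expect_error(zscore_fit(d, fit_rows = 1), "at least two rows")
  dc <- make_table(cbind(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_error(zscore_fit(dc), "a")
})

test_that("standardization is an exact affine bijection", {
  set.seed(21)
  d <- make_table(matrix(rnorm(80, sd = 5), 10, 8,
                         dimnames = list(NULL, paste0("d", 1:8))))
  st <- zscore_fit(d, fit_rows = 1:6)
  z <- zscore_apply(d, st)
  m_fit <- feature_matrix(z)[1:6, ]
  expect_equal(unname(colMeans(m_fit)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(sweep(m_fit, 2, colMeans(m_fit))^2))),
               rep(1, 8), tolerance = 1e-12)
  back <- zscore_invert(z, st)
  expect_equal(feature_matrix(back), feature_matrix(d), tolerance = 1e-10)
  # a value equal to the column mean maps to zero
  d0 <- make_table(cbind(a = c(1, 2, 3)))
  z0 <- zscore_apply(d0, zscore_fit(d0))
  expect_equal(z0$a[2], 0)
  # column mismatch is fatal
  expect_error(zscore_apply(d0, st), "do not match")
})

test_that("delimited input recognizes the standard error tokens", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,label,d1,d2,d3",
               "m1,1,0.5,N/A,2",
               "m2,0,1.5,3,Inf",
               "m3,1,,4,5",
               "m4,0,2.5,NaN,6",
               "m5,1,3.5,7,8"), path)
  d <- read_descriptor_matrix(path)
  expect_equal(nrow(d), 5)
  expect_true(all(!is.finite(feature_matrix(d)[1:4, ][cbind(1:4, c(2, 3, 1, 2))])))
  cleaned <- drop_error_rows(d)
  expect_equal(cleaned$id, "m5")
  # write/read round trip preserves values and labels
  out <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_matrix(cleaned, out)
  expect_equal(as.data.frame(read_descriptor_matrix(out)),
               strip_meta(cleaned))
  # separate label files are joined on id
  mpath <- withr::local_tempfile(fileext = ".csv")
  lpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,d1", "a,1", "b,2"), mpath)
  writeLines(c("id,label", "b,0", "a,1"), lpath)
  dl <- read_descriptor_matrix(mpath, lpath)
  expect_equal(dl$label, c(1L, 0L))
})
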