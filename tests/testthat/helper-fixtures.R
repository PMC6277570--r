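# Fixtures are built in code at test time: SDF files come from SMILES
# via Open Babel, descriptor tables from the package's own generator.

smiles_sdf <- function(smiles, path = tempfile(fileext = ".sdf")) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                   paste(smiles, collapse = "\n"))
  writeLines(txt, path)
  path
}

# A syntactically broken SDF record (bad counts line).
corrupt_sdf_record <- function() {
  c("corrupt molecule", "  bad generator", "",
    "999 bad counts line V2000",
    "M  END", "$$$$")
}

append_record <- function(path, record_lines) {
  cat(paste(c(record_lines, ""), collapse = "\n"),
      file = path, append = TRUE)
  path
}

# Small, fast training configuration for unit tests.
tiny_config <- function(...) {
  defaults <- list(hidden_dims = 8L, max_epochs = 20L,
                   early_stop_patience = 5L, batch_size = 32L,
                   dropout = 0, l2 = 1e-5, seed = 1L)
  do.call(training_config, utils::modifyList(defaults, list(...)))
}

# The scaled synthetic benchmark emulating a heavily imbalanced
# drug/non-drug setting (about 1:50), used by the acceptance tests.
benchmark_data <- function(seed) {
  simulate_descriptors(n_pos = 200, n_neg = 10000, n_features = 100,
                       latent_dim = 10, class_shift = 3, noise_sd = 0.5,
                       seed = seed)
}

benchmark_config <- function(seed) {
  training_config(hidden_dims = 64L, max_epochs = 15L,
                  early_stop_patience = 3L, seed = seed)
}

# Check that `row` can be written as x_i + u * (x_nn - x_i) for some
# minority row i, one of its k nearest minority neighbours nn, and
# u in [0, 1]. Returns TRUE/FALSE.
is_smote_interpolant <- function(row, minority, k, tol = 1e-8) {
  n <- nrow(minority)
  D <- as.matrix(stats::dist(minority))
  diag(D) <- Inf
  for (i in seq_len(n)) {
    nns <- order(D[i, ])[seq_len(min(k, n - 1L))]
    for (j in nns) {
      dir <- minority[j, ] - minority[i, ]
      dlt <- row - minority[i, ]
      denom <- sum(dir^2)
      if (denom == 0) {
        if (sqrt(sum(dlt^2)) < tol) return(TRUE)
        next
      }
      u <- sum(dlt * dir) / denom
      if (u >= -tol && u <= 1 + tol &&
          sqrt(sum((dlt - u * dir)^2)) < tol * (1 + sqrt(denom)))
        return(TRUE)
    }
  }
  FALSE
}
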