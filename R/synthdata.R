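#' Simulate a two-class molecular descriptor table
#'
#' Generates labeled synthetic descriptor data with the statistical
#' structure that descriptor matrices computed from real compound
#' collections exhibit: strongly correlated columns arising from a
#' low-dimensional latent structure, a controllable separation between
#' the two classes, uninformative constant descriptors, and sporadic
#' missing entries.
#'
#' The generative model draws, for each molecule, a latent factor vector
#' `z` of dimension `latent_dim` from an isotropic Gaussian whose mean is
#' `+class_shift/2` (positive class) or `-class_shift/2` (negative class)
#' in every latent coordinate. Observed descriptors are `z %*% A` plus
#' isotropic Gaussian noise of standard deviation `noise_sd`, where `A`
#' is a fixed `latent_dim x n_features` standard-Gaussian loading matrix
#' drawn once per seed. With `noise_sd = 0` the descriptor matrix has
#' rank exactly `latent_dim`. Constant descriptor columns and missing
#' entries are then injected so the post-processing stage has something
#' to do.
#'
#' @param n_pos,n_neg Number of positive (drug-like) and negative rows.
#' @param n_features Number of informative descriptor columns; defaults
#'   to 700, the order of magnitude of a typical 2D descriptor set.
#' @param latent_dim Intrinsic dimensionality of the data.
#' @param class_shift Separation between class means along every latent
#'   coordinate, in latent standard-deviation units.
#' @param noise_sd Standard deviation of the ambient descriptor noise.
#' @param n_constant_cols Number of constant columns appended.
#' @param na_fraction Fraction of descriptor entries replaced by `NA`.
#' @param seed Integer seed; identical seed and sizes give an identical
#'   table.
#' @return A descriptor table (tibble) with columns `id`, `label`, and
#'   descriptors `d0001 ...`; positive rows first. The attribute
#'   `"truth"` carries the generating parameters, the loading matrix and
#'   the Bayes error of the optimal linear rule, for use as test oracles.
#' @examples
#' d <- simulate_descriptors(20, 80, n_features = 30, seed = 1)
#' dplyr::count(d, label)
#' @export
simulate_descriptors <- function(n_pos,
                                 n_neg,
                                 n_features = 700,
                                 latent_dim = 10,
                                 class_shift = 3,
                                 noise_sd = 0.5,
                                 n_constant_cols = 0,
                                 na_fraction = 0,
                                 seed = NULL) {
  stopifnot(n_pos >= 1, n_neg >= 1, latent_dim >= 1, n_features >= 1)
  if (latent_dim > n_features) {
    abort("`latent_dim` must not exceed `n_features`")
  }
  if (na_fraction < 0 || na_fraction >= 1) {
    abort("`na_fraction` must be in [0, 1)")
  }
  n <- n_pos + n_neg
  .with_seed(seed, {
    label <- c(rep(1L, n_pos), rep(0L, n_neg))
    shift <- ifelse(label == 1L, class_shift / 2, -class_shift / 2)
    z <- matrix(stats::rnorm(n * latent_dim), n, latent_dim) + shift
    loading <- matrix(stats::rnorm(latent_dim * n_features),
                      latent_dim, n_features)
    x <- z %*% loading
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(n * n_features, sd = noise_sd),
                      n, n_features)
    }
    if (n_constant_cols > 0) {
      const <- matrix(rep(seq_len(n_constant_cols), each = n),
                      n, n_constant_cols)
      x <- cbind(x, const)
    }
    if (na_fraction > 0) {
      n_entries <- length(x)
      idx <- which(stats::runif(n_entries) < na_fraction)
      x[idx] <- NA_real_
    }
    total_cols <- n_features + n_constant_cols
    colnames(x) <- sprintf("d%04d", seq_len(total_cols))
    out <- dplyr::bind_cols(
      tibble(id = sprintf("mol%06d", seq_len(n)), label = label),
      as_tibble(x)
    )
    attr(out, "truth") <- list(
      loading = loading,
      latent_dim = latent_dim,
      class_shift = class_shift,
      noise_sd = noise_sd,
      n_constant_cols = n_constant_cols,
      na_fraction = na_fraction,
      seed = seed,
      bayes_error = bayes_error(class_shift, latent_dim)
    )
    out
  })
}

#' Bayes error of the optimal linear rule for the simulated model
#'
#' For the latent-factor generative model of [simulate_descriptors()]
#' (noise-free, equal priors), the two class-conditional latent
#' distributions are unit Gaussians whose means differ by `class_shift`
#' in each of `latent_dim` coordinates, i.e. a Mahalanobis separation of
#' `class_shift * sqrt(latent_dim)`. The optimal rule's error rate has
#' the closed form `pnorm(-separation / 2)`.
#'
#' @param class_shift,latent_dim As in [simulate_descriptors()].
#' @return The minimal achievable misclassification rate under equal
#'   priors.
#' @export
bayes_error <- function(class_shift, latent_dim) {
  stats::pnorm(-abs(class_shift) * sqrt(latent_dim) / 2)
}
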