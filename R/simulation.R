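#' Simulation settings
#'
#' @param n_cells Number of cells to simulate (C).
#' @param gamma Sparsity adjustment factor multiplying every Poisson mean;
#'   default 1.  Values below 1 make the simulated matrix sparser, above 1
#'   denser.
#' @param noise_mean,noise_sd Parameters of the optional additive Gaussian
#'   noise applied to final counts; the default (0, 0) disables noise.
#' @param seed Integer seed; a run is bit-reproducible given the seed.
#' @return A `simulation_settings` object.
#' @export
simulation_settings <- function(n_cells, gamma = 1, noise_mean = 0,
                                noise_sd = 0, seed = 1L) {
  n_cells <- as.integer(n_cells)
  stopifnot(n_cells >= 1L, gamma > 0, noise_sd >= 0, is.finite(noise_mean))
  structure(list(n_cells = n_cells, gamma = gamma, noise_mean = noise_mean,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_settings")
}

#' Sample library sizes from the Gaussian mixture
#'
#' For each cell, picks component 1 with probability `w` (else component
#' 2), draws log2 library size from the chosen Gaussian, and returns the
#' continuous value `2^draw` (library sizes are kept continuous: they act
#' only as Poisson scale factors downstream).
#'
#' Consumes the current RNG stream; call [set.seed()] (or use
#' [simulate_matrix()], which seeds once for the whole pipeline) for
#' reproducibility.
#'
#' @param model A `library_size_model`.
#' @param n_cells Number of draws.
#' @return Positive numeric vector of length `n_cells`.
#' @export
sample_library_sizes <- function(model, n_cells) {
  stopifnot(inherits(model, "library_size_model"), n_cells >= 1)
  first <- stats::runif(n_cells) < model$w
  mu <- ifelse(first, model$mu1, model$mu2)
  sg <- ifelse(first, model$sigma1, model$sigma2)
  2^stats::rnorm(n_cells, mean = mu, sd = sg)
}

#' Sample the Bernoulli non-zero mask
#'
#' Draws independent indicators `X[j, i] ~ Bernoulli(p_j)`: which entries
#' of the simulated matrix are allowed to be non-zero.  Entries are drawn
#' bin-fastest (column-major), one cell after another.
#'
#' @param p Per-bin non-zero proportions, values in \[0, 1\].
#' @param n_cells Number of columns.
#' @return A sparse B x `n_cells` 0/1 matrix (`dgCMatrix`).
#' @export
sample_nonzero_mask <- function(p, n_cells) {
  p <- as.numeric(p)
  stopifnot(all(p >= 0), all(p <= 1), n_cells >= 1)
  B <- length(p)
  draws <- stats::rbinom(B * n_cells, size = 1L, prob = p)  # p recycled bin-fastest
  idx <- which(draws == 1L)
  Matrix::sparseMatrix(i = (idx - 1L) %% B + 1L,
                       j = (idx - 1L) %/% B + 1L,
                       x = 1,
                       dims = c(B, n_cells))
}

#' Bin means from simulated non-zero proportions
#'
#' Evaluates the quadratic bin-mean model at the simulated proportions:
#' `m_j = beta0 + beta1 * p_j + beta2 * p_j^2`.  Negative values are
#' clamped to 0 and bins with `p_j == 0` are forced to 0 so fully closed
#' bins contribute no Poisson mass.
#'
#' @param sim_nonzero_prop Simulated per-bin non-zero proportions (row
#'   means of the Bernoulli mask).
#' @param beta0,beta1,beta2 Quadratic coefficients.
#' @return Non-negative numeric vector of bin means.
#' @export
compute_bin_means <- function(sim_nonzero_prop, beta0, beta1, beta2) {
  p <- as.numeric(sim_nonzero_prop)
  stopifnot(all(p >= 0), all(p <= 1))
  m <- beta0 + beta1 * p + beta2 * p^2
  m[m < 0] <- 0
  m[p == 0] <- 0
  if (all(m == 0)) {
    stop("all simulated bin means are zero; the Poisson scaling ",
         "denominator vanishes (degenerate profile)", call. = FALSE)
  }
  m
}

#' Sample final counts: masked Poisson draws
#'
#' Each mask-allowed entry receives `Poisson(gamma * c[j, i])` where
#' `c[j, i] = l_i * m_j / sum(m)` is the cell's library size apportioned to
#' bin j by its relative bin mean.  Masked-out entries are exactly zero;
#' masked-in entries may still be zero by Poisson chance, so realized
#' sparsity is at least the Bernoulli sparsity.
#'
#' @param library_sizes Per-cell library sizes (length C).
#' @param bin_means Non-negative bin means (length B, not all zero).
#' @param mask B x C 0/1 sparse matrix.
#' @param gamma Sparsity adjustment factor (> 0).
#' @return Sparse B x C integer count matrix (`dgCMatrix`).
#' @export
sample_counts <- function(library_sizes, bin_means, mask, gamma = 1) {
  l <- as.numeric(library_sizes)
  m <- as.numeric(bin_means)
  stopifnot(gamma > 0, all(m >= 0))
  S <- sum(m)
  if (S <= 0) stop("sum of bin means must be positive", call. = FALSE)
  mask <- as_dgc(mask)
  if (nrow(mask) != length(m) || ncol(mask) != length(l)) {
    stop("mask dimensions do not match bin_means / library_sizes",
         call. = FALSE)
  }
  i <- mask@i + 1L
  j <- rep.int(seq_len(ncol(mask)), diff(mask@p))
  mu <- gamma * l[j] * m[i] / S
  if (any(mu > 2^31)) {
    stop("Poisson means exceed 2^31; library sizes or gamma are ",
         "implausibly large", call. = FALSE)
  }
  x <- stats::rpois(length(mu), mu)
  Matrix::drop0(Matrix::sparseMatrix(i = i, j = j, x = as.numeric(x),
                                     dims = dim(mask)))
}

#' Optional additive Gaussian noise
#'
#' Adds `int(N(noise_mean, noise_sd))` independently to every entry
#' (including zeros), where `int()` rounds half away from zero, then
#' clamps at 0.  With `noise_mean = 0, noise_sd = 0` (the default
#' configuration) this is the identity and consumes no random numbers.
#' Noise can shift the library-size distribution and the sparsity of the
#' output away from the profile; it exists to blur group differences for
#' harder benchmarking scenarios.
#'
#' @param counts Sparse count matrix.
#' @param noise_mean,noise_sd Gaussian noise parameters (`noise_sd >= 0`).
#' @return Sparse non-negative integer matrix of the same dimensions.
#' @export
add_noise <- function(counts, noise_mean = 0, noise_sd = 0) {
  stopifnot(noise_sd >= 0)
  if (noise_mean == 0 && noise_sd == 0) {
    return(counts)
  }
  dense <- as.matrix(counts)
  noise <- round_half_away(stats::rnorm(length(dense), noise_mean, noise_sd))
  as_dgc(pmax(dense + noise, 0))
}

#' Simulate a bin-by-cell matrix from a profile
#'
#' Runs the full generative pipeline under a single seed: sample library
#' sizes from the Gaussian mixture, draw the Bernoulli non-zero mask,
#' compute simulated non-zero proportions (mask row means) and quadratic
#' bin means, draw masked Poisson counts scaled by `gamma`, and optionally
#' add integer Gaussian noise.  The RNG stream order is fixed (library
#' sizes, mask, Poisson draws over mask entries in column-major order,
#' noise), so a given `(profile, settings)` pair is bit-reproducible.
#'
#' @param profile A `simulation_profile`.
#' @param settings A `simulation_settings`.
#' @return List with `matrix` (a `bin_cell_matrix` with barcodes
#'   `simcell_000001`, ...) and `draw` (intermediate quantities:
#'   `library_sizes`, `mask`, `sim_nonzero_prop`, `bin_means`,
#'   `poisson_means`, plus realized `sparsity`).
#' @export
simulate_matrix <- function(profile, settings) {
  stopifnot(inherits(profile, "simulation_profile"),
            inherits(settings, "simulation_settings"))
  set.seed(settings$seed)
  bm <- profile$bin_model
  B <- nrow(profile$bins)
  C <- settings$n_cells

  l <- sample_library_sizes(profile$library_model, C)
  mask <- sample_nonzero_mask(bm$p, C)
  p_sim <- Matrix::rowMeans(mask)

  if (all(p_sim == 0)) {
    # every entry masked out: the matrix is all zeros and no Poisson
    # scaling is needed
    m_sim <- numeric(B)
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(B, C))
    pois_mu <- counts
  } else {
    m_sim <- compute_bin_means(p_sim, bm$beta0, bm$beta1, bm$beta2)
    counts <- sample_counts(l, m_sim, mask, gamma = settings$gamma)
    i <- mask@i + 1L
    j <- rep.int(seq_len(C), diff(mask@p))
    pois_mu <- Matrix::sparseMatrix(
      i = i, j = j, x = settings$gamma * l[j] * m_sim[i] / sum(m_sim),
      dims = c(B, C))
  }
  counts <- add_noise(counts, settings$noise_mean, settings$noise_sd)

  mat <- bin_cell_matrix(counts, profile$bins,
                         sprintf("simcell_%06d", seq_len(C)),
                         group_label = profile$group_label)
  draw <- list(library_sizes = l,
               mask = mask,
               sim_nonzero_prop = p_sim,
               bin_means = m_sim,
               poisson_means = pois_mu,
               sparsity = 1 - length(counts@x) / (as.numeric(B) * C),
               settings = settings)
  list(matrix = mat, draw = draw)
}
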