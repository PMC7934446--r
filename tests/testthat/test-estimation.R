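gmm_draws <- function(n, mu1, s1, mu2, s2, w, seed) {
  # reference sampler, independent of the package's sampling path
  set.seed(seed)
  first <- stats::runif(n) < w
  2^stats::rnorm(n, ifelse(first, mu1, mu2), ifelse(first, s1, s2))
}

test_that("EM recovers a well-separated two-mode mixture", {
  x <- gmm_draws(10000, 11, 0.5, 13.5, 0.6, 0.4, seed = 101)
  fit <- estimate_library_model(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu1 - 11), 0.1)
  expect_lt(abs(fit$mu2 - 13.5), 0.1)
  expect_lt(abs(fit$sigma1 - 0.5), 0.05)
  expect_lt(abs(fit$sigma2 - 0.6), 0.05)
  expect_lt(abs(fit$w - 0.4), 0.03)
})

test_that("EM agrees with an independent mixture fitter (mclust)", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  x <- gmm_draws(5000, 10, 0.4, 13, 0.7, 0.3, seed = 55)
  fit <- estimate_library_model(x)
  mc <- mclust::Mclust(log2(x), G = 2, modelNames = "V", verbose = FALSE)
  ord <- order(mc$parameters$mean)
  expect_lt(abs(fit$mu1 - mc$parameters$mean[ord[1]]), 0.02)
  expect_lt(abs(fit$mu2 - mc$parameters$mean[ord[2]]), 0.02)
  expect_lt(abs(fit$w - mc$parameters$pro[ord[1]]), 0.01)
  expect_lt(abs(fit$sigma1 -
                  sqrt(mc$parameters$variance$sigmasq[ord[1]])), 0.02)
})

test_that("degenerate and single-mode inputs are handled", {
  fit <- estimate_library_model(rep(2^12, 50))
  expect_equal(fit$mu1, 12)
  expect_equal(fit$mu2, 12)
  expect_gte(fit$sigma1, 1e-3)   # variance floor

  x <- 2^stats::rnorm(5000, 12, 0.5)
  f1 <- estimate_library_model(x, n_components = 1)
  expect_equal(f1$w, 1)
  expect_identical(f1$mu1, f1$mu2)
  expect_lt(abs(f1$mu1 - 12), 0.05)

  expect_error(estimate_library_model(c(rep(100, 5), 0, rep(100, 5))),
               "positive")
  expect_error(estimate_library_model(rep(100, 9)), "at least 10")
})

test_that("non-zero proportions are exact fractions of non-zero cells", {
  bins <- make_bins(chrom_sizes("chrT", 15000), bin_width = 5000L)
  m <- bin_cell_matrix(matrix(c(0, 1, 0, 2, 0, 0), nrow = 3), bins,
                       c("a", "b"))
  expect_equal(estimate_nonzero_proportions(m), c(0.5, 0.5, 0))

  m2 <- rand_bcm(B = 500, C = 40, seed = 9)
  expect_equal(estimate_nonzero_proportions(m2),
               unname(apply(as.matrix(m2$counts), 1, function(x) mean(x > 0))))
  expect_equal(max(estimate_nonzero_proportions(rand_bcm(B = 5, C = 30,
                                                         lambda = 5))), 1)
})

test_that("normalization rescales every cell to the median library size", {
  bins <- make_bins(chrom_sizes("chrT", 10000), bin_width = 5000L)
  m1 <- bin_cell_matrix(matrix(c(2, 0), 2), bins, "only")
  expect_equal(as.matrix(normalize_matrix(m1)), matrix(c(2, 0), 2),
               ignore_attr = TRUE)

  m2 <- bin_cell_matrix(matrix(c(2, 0, 0, 4), 2), bins, c("a", "b"))
  norm <- as.matrix(normalize_matrix(m2))
  expect_equal(norm, matrix(c(3, 0, 0, 3), 2), ignore_attr = TRUE)

  for (seed in 1:3) {
    m <- rand_bcm(B = 80, C = 15, seed = seed, lambda = 1)
    lib <- Matrix::colSums(m$counts)
    if (any(lib == 0)) next
    cs <- Matrix::colSums(normalize_matrix(m))
    expect_equal(unname(cs), rep(stats::median(lib), ncol(m$counts)))
  }

  m0 <- bin_cell_matrix(matrix(c(1, 0, 0, 0), 2), bins, c("a", "b"))
  expect_error(normalize_matrix(m0), "zero library size")
})

test_that("quadratic OLS is exact on noiseless data and tight with noise", {
  p <- seq(0, 1, by = 0.1)
  y <- 0.1 + 2 * p + 3 * p^2
  fit <- fit_bin_mean_polynomial(p, y)
  expect_equal(c(fit$beta0, fit$beta1, fit$beta2), c(0.1, 2, 3),
               tolerance = 1e-10)

  set.seed(42)
  p <- stats::runif(5000)
  y <- 0.1 + 2 * p + 3 * p^2 + stats::rnorm(5000, 0, 0.01)
  fit <- fit_bin_mean_polynomial(p, y)
  expect_lt(abs(fit$beta0 - 0.1), 0.02)
  expect_lt(abs(fit$beta1 - 2), 0.02)
  expect_lt(abs(fit$beta2 - 3), 0.02)

  expect_error(fit_bin_mean_polynomial(rep(0.5, 10), stats::runif(10)),
               "degenerate")
})

test_that("estimate_profile composes estimators and drops empty cells", {
  fx <- small_fixture(seed = 21)
  pr <- suppressWarnings(estimate_profile(fx$matrix))
  expect_s3_class(pr, "simulation_profile")
  expect_length(pr$bin_model$p, nrow(fx$matrix$bins))
  expect_gt(stats::cor(pr$bin_model$p, fx$p), 0.95)
  expect_equal(pr$n_cells_source, ncol(fx$matrix$counts))

  # an all-zero cell is dropped with a warning and not counted
  m <- fx$matrix
  counts <- cbind(m$counts, Matrix::sparseMatrix(i = integer(0),
                                                 j = integer(0), x = numeric(0),
                                                 dims = c(nrow(m$counts), 1)))
  m2 <- bin_cell_matrix(counts, m$bins, c(m$barcodes, "empty_cell"))
  expect_warning(pr2 <- estimate_profile(m2), "zero library size")
  expect_equal(pr2$n_cells_source, ncol(m$counts))

  expect_equal(suppressWarnings(
    estimate_profile(fx$matrix, "unimodal"))$library_model$w, 1)
})

test_that("platform_hint auto picks the BIC-preferred mode count", {
  # clean single-Gaussian library sizes: one component wins on BIC
  x <- gmm_draws(2000, 12, 0.4, 12, 0.4, 1, seed = 5)
  f1 <- estimate_library_model(x, n_components = 1)
  # the 2-component fit may drift without converging on unimodal data;
  # its non-convergence warning is expected here
  f2 <- suppressWarnings(estimate_library_model(x, n_components = 2))
  expect_lte(f1$bic, f2$bic)

  # well-separated bimodal fixture: auto keeps two components
  fx_bi <- small_fixture(seed = 6, n_cells = 600)
  pr2 <- suppressWarnings(estimate_profile(fx_bi$matrix, "auto"))
  expect_lt(pr2$library_model$w, 1)
  expect_gt(abs(pr2$library_model$mu2 - pr2$library_model$mu1), 1)
})

test_that("estimation is invariant to cell order and equivariant in bins", {
  fx <- small_fixture(seed = 31, n_cells = 200, n_bins = 150)
  m <- fx$matrix
  set.seed(1)
  cperm <- sample(ncol(m$counts))
  mp <- bin_cell_matrix(m$counts[, cperm], m$bins, m$barcodes[cperm])
  pr <- suppressWarnings(estimate_profile(m))
  prp <- suppressWarnings(estimate_profile(mp))
  expect_equal(prp$library_model[c("mu1", "sigma1", "mu2", "sigma2", "w")],
               pr$library_model[c("mu1", "sigma1", "mu2", "sigma2", "w")])
  expect_equal(prp$bin_model$p, pr$bin_model$p)

  rperm <- sample(nrow(m$counts))
  mr <- m
  mr$counts <- m$counts[rperm, ]
  expect_equal(estimate_nonzero_proportions(mr),
               estimate_nonzero_proportions(m)[rperm])
})

test_that("profile serialization round trips through JSON + TSV + BED", {
  fx <- small_fixture(seed = 41, n_cells = 150, n_bins = 100)
  pr <- suppressWarnings(estimate_profile(fx$matrix))
  d <- withr::local_tempdir()
  write_profile(pr, d)
  pr2 <- read_profile(d)
  for (f in c("mu1", "sigma1", "mu2", "sigma2", "w")) {
    expect_equal(pr2$library_model[[f]], pr$library_model[[f]])
  }
  expect_equal(pr2$bin_model$p, pr$bin_model$p, tolerance = 1e-12)
  expect_equal(pr2$bin_model$beta2, pr$bin_model$beta2)
  expect_equal(pr2$bins, pr$bins)
  expect_equal(pr2$n_cells_source, pr$n_cells_source)
})
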