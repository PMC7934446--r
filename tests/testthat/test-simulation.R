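test_that("library-size sampling hits the mixture's moments and limits", {
  set.seed(1)
  pm <- library_size_model(10, 1e-9, 10, 1e-9, w = 1)
  expect_equal(sample_library_sizes(pm, 50), rep(1024, 50), tolerance = 1e-6)

  set.seed(2)
  m <- library_size_model(10, 0.5, 14, 0.5, w = 0.5)
  l <- sample_library_sizes(m, 10000)
  expect_lt(abs(mean(log2(l)) - 12), 0.1)

  set.seed(3)
  m0 <- library_size_model(10, 1e-9, 14, 1e-9, w = 0)
  expect_equal(sample_library_sizes(m0, 100), rep(2^14, 100),
               tolerance = 1e-6)
})

test_that("Bernoulli mask respects endpoints and concentrates on p", {
  set.seed(4)
  p <- c(0, 1, 0.3)
  X <- sample_nonzero_mask(p, 10000)
  pp <- Matrix::rowMeans(X)
  expect_equal(pp[1], 0)
  expect_equal(pp[2], 1)
  expect_lt(abs(pp[3] - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  expect_true(all(X@x == 1))
})

test_that("mask row means converge to p as C grows", {
  p <- stats::qbeta(stats::ppoints(50), 0.5, 8)
  for (C in c(100, 1000, 10000)) {
    set.seed(C)
    pp <- Matrix::rowMeans(sample_nonzero_mask(p, C))
    # every bin within 4 binomial SDs (plus slack for tiny p)
    expect_true(all(abs(pp - p) <= 4 * sqrt(p * (1 - p) / C) + 2 / C))
  }
})

test_that("bin means follow the clamped quadratic of simulated proportions", {
  expect_equal(compute_bin_means(c(0.3, 0.7), 0, 1, 0), c(0.3, 0.7))
  expect_equal(compute_bin_means(0.5, 0.05, 2, 1), 1.3)
  expect_equal(compute_bin_means(c(0.01, 0.5), -0.1, 0, 0.8), c(0, 0.1))
  # p = 0 forces m = 0 even with positive intercept
  expect_equal(compute_bin_means(c(0, 0.5), 0.2, 1, 0), c(0, 0.7))
  expect_error(compute_bin_means(c(0, 0), 0.5, 1, 1), "zero")
})

test_that("Poisson totals conserve library sizes under a full mask", {
  B <- 1000; C <- 500
  mask <- Matrix::Matrix(1, B, C, sparse = TRUE)
  mprime <- rep(1, B)
  l <- rep(5000, C)
  set.seed(5)
  counts <- sample_counts(l, mprime, mask, gamma = 1)
  totals <- Matrix::colSums(counts)
  expect_lt(abs(mean(totals) - 5000), 3 * sqrt(5000 / C))

  # expected totals scale linearly in gamma
  set.seed(6)
  t_half <- Matrix::colSums(sample_counts(l, mprime, mask, gamma = 0.5))
  expect_lt(abs(mean(t_half) - 2500), 3 * sqrt(2500 / C))
  set.seed(7)
  t_twice <- Matrix::colSums(sample_counts(l, mprime, mask, gamma = 2))
  expect_lt(abs(mean(t_twice) - 10000), 3 * sqrt(10000 / C))
})

test_that("masking and degenerate limits behave", {
  B <- 20; C <- 10
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(B, C))
  set.seed(8)
  out <- sample_counts(rep(1000, C), rep(1, B), empty)
  expect_equal(sum(out), 0)

  # gamma -> 0+ limit: Poisson(~0) draws are all zero
  full <- Matrix::Matrix(1, B, C, sparse = TRUE)
  set.seed(9)
  out0 <- sample_counts(rep(1000, C), rep(1, B), full, gamma = 1e-12)
  expect_equal(sum(out0), 0)

  expect_error(sample_counts(rep(2^60, C), rep(1, B), full), "2\\^31")
  # counts are zero wherever the mask is zero
  set.seed(10)
  half <- sample_nonzero_mask(rep(0.5, B), C)
  cts <- sample_counts(rep(5000, C), rep(1, B), half)
  expect_true(all(as.matrix(cts)[as.matrix(half) == 0] == 0))
})

test_that("additive noise is identity when disabled and clamps at zero", {
  m <- rand_bcm(B = 40, C = 12, seed = 11)$counts
  expect_identical(add_noise(m, 0, 0), m)

  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                               x = numeric(0), dims = c(30, 5))
  set.seed(12)
  noised <- add_noise(zero, -5, 0.1)
  expect_equal(sum(noised), 0)

  set.seed(13)
  down <- add_noise(m, -0.3, 0.3)
  dm <- as.matrix(down)
  expect_true(all(dm >= 0))
  expect_true(all(dm == round(dm)))
  # negative-mean noise cannot decrease sparsity
  expect_gte(mean(dm == 0), mean(as.matrix(m) == 0))
  # zeros can gain counts: noise touches every entry
  set.seed(14)
  up <- as.matrix(add_noise(zero, 2, 0.5))
  expect_gt(sum(up), 0)
})

test_that("simulate_matrix is reproducible and draw invariants hold", {
  profile <- default_profile("toy-bimodal")
  st <- simulation_settings(100, seed = 77)
  r1 <- simulate_matrix(profile, st)
  r2 <- simulate_matrix(profile, st)
  expect_identical(as.matrix(r1$matrix$counts), as.matrix(r2$matrix$counts))
  expect_identical(r1$draw$library_sizes, r2$draw$library_sizes)

  r3 <- simulate_matrix(profile, simulation_settings(100, seed = 78))
  expect_false(identical(as.matrix(r1$matrix$counts),
                         as.matrix(r3$matrix$counts)))

  # Eq-3 identity and mask consistency
  expect_equal(r1$draw$sim_nonzero_prop, Matrix::rowMeans(r1$draw$mask))
  cm <- as.matrix(r1$matrix$counts)
  expect_true(all(cm[as.matrix(r1$draw$mask) == 0] == 0))
  expect_true(all(cm >= 0))
  expect_identical(r1$matrix$barcodes[1], "simcell_000001")

  # degenerate: one cell, fully closed genome
  closed <- profile
  closed$bin_model$p[] <- 0
  out <- simulate_matrix(closed, simulation_settings(1, seed = 1))
  expect_equal(sum(out$matrix$counts), 0)
  expect_equal(dim(out$matrix$counts), c(2000L, 1L))
})

test_that("realized sparsity decreases as gamma increases", {
  profile <- default_profile("toy-bimodal")
  sparsity <- vapply(c(0.5, 1, 2), function(g) {
    simulate_matrix(profile,
                    simulation_settings(200, gamma = g,
                                        seed = 1000 + g * 10))$draw$sparsity
  }, numeric(1))
  expect_true(all(diff(sparsity) < 0))
})
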