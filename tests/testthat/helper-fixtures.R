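# small in-code fixtures shared across test files

# the worked 2x2 example: counts [[3, 0], [0, 1]]
tiny_bcm <- function() {
  bins <- make_bins(chrom_sizes("chrT", 10000), bin_width = 5000L)
  bin_cell_matrix(matrix(c(3, 0, 0, 1), nrow = 2), bins, c("cellA", "cellB"))
}

# random Poisson bin_cell_matrix on a toy chromosome
rand_bcm <- function(B = 50, C = 20, seed = 1, lambda = 0.5) {
  set.seed(seed)
  counts <- matrix(stats::rpois(B * C, lambda), nrow = B)
  bins <- make_bins(chrom_sizes("chrT", B * 1000), bin_width = 1000L)
  bin_cell_matrix(counts, bins, sprintf("cell%03d", seq_len(C)))
}

# small fast fixture for estimation / simulation round trips
small_fixture <- function(seed = 7, n_cells = 300, n_bins = 400) {
  make_fixture(fixture_spec(n_cells = n_cells, n_bins = n_bins, seed = seed))
}
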