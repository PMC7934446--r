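#' Specification for a self-contained synthetic "real" dataset
#'
#' Fixtures play the role of an input real dataset with known ground
#' truth: per-bin non-zero proportions are drawn from a sparse mixture (a
#' point mass at 0 for closed bins plus a Beta distribution for open
#' ones), and a matrix is generated from the implied profile.  Estimators
#' can then be checked against the generating parameters, and simulators
#' against the generated matrix, with no external data.
#'
#' Defaults emulate a droplet-style cell group at desk scale: 1000 cells,
#' 2000 5-kbp bins, a bimodal library-size mixture
#' `0.4 N(11, 0.5^2) + 0.6 N(13.5, 0.6^2)` (log2 scale), 60% fully closed
#' bins with the open ones' proportions from Beta(0.5, 8) (median around
#' 0.02, matching the heavy sparsity of real bin-by-cell matrices), and a
#' mildly convex bin-mean curve.  These are documented synthetic values,
#' not estimates from any particular dataset.
#'
#' @param n_cells,n_bins Matrix dimensions.
#' @param library_model A `library_size_model`.
#' @param p_zero_fraction Expected fraction of bins with `p = 0`.
#' @param p_shape1,p_shape2 Beta parameters for the open bins.
#' @param beta Length-3 numeric: quadratic bin-mean coefficients
#'   (must be non-negative over \[0, 1\]).
#' @param bin_width Bin width for the synthetic chromosome.
#' @param seed Integer seed; fixtures are deterministic given the spec.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_cells = 1000L, n_bins = 2000L,
                         library_model = library_size_model(
                           11, 0.5, 13.5, 0.6, w = 0.4),
                         p_zero_fraction = 0.6,
                         p_shape1 = 0.5, p_shape2 = 8,
                         beta = c(0.02, 2.5, 6),
                         bin_width = 5000L,
                         seed = 1L) {
  stopifnot(n_cells >= 1, n_bins >= 3,
            inherits(library_model, "library_size_model"),
            p_zero_fraction >= 0, p_zero_fraction < 1,
            p_shape1 > 0, p_shape2 > 0, length(beta) == 3L)
  # simulation clamps negative means, but a fixture should have a cleanly
  # non-negative mean curve over the whole [0, 1] proportion range
  grid <- seq(0, 1, by = 0.001)
  if (min(beta[[1L]] + beta[[2L]] * grid + beta[[3L]] * grid^2) < 0) {
    stop("beta implies negative bin means on [0, 1]", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), n_bins = as.integer(n_bins),
                 library_model = library_model,
                 p_zero_fraction = p_zero_fraction,
                 p_shape1 = p_shape1, p_shape2 = p_shape2,
                 beta = as.numeric(beta), bin_width = as.integer(bin_width),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# one synthetic chromosome exactly covered by n_bins bins
toy_bins <- function(n_bins, bin_width = 5000L) {
  make_bins(chrom_sizes("chrS", as.numeric(n_bins) * bin_width),
            bin_width = bin_width)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws per-bin proportions from the spec's sparse mixture, assembles the
#' generating `simulation_profile`, and simulates a matrix from it.  Both
#' the matrix (the pretend "real" input) and the generating profile (the
#' ground truth) are returned; the whole construction is deterministic
#' given `spec$seed`.
#'
#' @param spec A `fixture_spec`.
#' @return List with `matrix` (a `bin_cell_matrix`), `profile` (the
#'   generating `simulation_profile`), and `p` (the generating
#'   proportions, identical to `profile$bin_model$p`).
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  closed <- stats::runif(spec$n_bins) < spec$p_zero_fraction
  p <- stats::rbeta(spec$n_bins, spec$p_shape1, spec$p_shape2)
  p[closed] <- 0
  if (all(p == 0)) {
    stop("degenerate fixture: every bin closed; lower p_zero_fraction",
         call. = FALSE)
  }
  lm <- spec$library_model
  profile <- simulation_profile(
    library_model = lm,
    bin_model = bin_model(p, spec$beta[[1L]], spec$beta[[2L]], spec$beta[[3L]],
                          median_library_size =
                            2^(lm$w * lm$mu1 + (1 - lm$w) * lm$mu2)),
    bins = toy_bins(spec$n_bins, spec$bin_width),
    n_cells_source = spec$n_cells,
    group_label = "fixture"
  )
  sim_seed <- (spec$seed * 7919L + 1L) %% .Machine$integer.max
  out <- simulate_matrix(profile,
                         simulation_settings(spec$n_cells, seed = sim_seed))
  list(matrix = out$matrix, profile = profile, p = p)
}

#' Built-in default simulation profiles
#'
#' Fully specified profiles usable without any input data, on a 2000-bin
#' synthetic chromosome.  `"toy-bimodal"` uses the bimodal library-size
#' mixture typical of droplet platforms; `"toy-unimodal"` a single mode
#' (`w = 1`) as seen on plate-based platforms.  Proportions follow the
#' same sparse pattern as [fixture_spec()] but laid out deterministically
#' (no random draws), so the profile is a constant of the package.  All
#' parameter values are documented synthetic choices, not estimates from
#' any published dataset.
#'
#' @param tag `"toy-bimodal"` or `"toy-unimodal"`.
#' @return A `simulation_profile`.
#' @export
default_profile <- function(tag = c("toy-bimodal", "toy-unimodal")) {
  tag <- match.arg(tag)
  n_bins <- 2000L
  idx <- seq_len(n_bins) - 1L
  open <- idx %% 5L >= 3L                      # 40% open bins, interleaved
  p <- numeric(n_bins)
  p[open] <- stats::qbeta(stats::ppoints(sum(open)), 0.5, 8)
  lm <- switch(tag,
    "toy-bimodal" = library_size_model(11, 0.5, 13.5, 0.6, w = 0.4),
    "toy-unimodal" = library_size_model(12, 0.5, 12, 0.5, w = 1))
  simulation_profile(
    library_model = lm,
    bin_model = bin_model(p, 0.02, 2.5, 6,
                          median_library_size =
                            2^(lm$w * lm$mu1 + (1 - lm$w) * lm$mu2)),
    bins = toy_bins(n_bins),
    n_cells_source = NA_integer_,
    group_label = tag
  )
}
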