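#' Library-size model: two-component Gaussian mixture on log2 scale
#'
#' Container for the parameters of the library-size model: log2 library
#' sizes are distributed as `w * N(mu1, sigma1^2) + (1 - w) * N(mu2,
#' sigma2^2)`.  Components are stored in canonical order `mu1 <= mu2`;
#' `w` is the weight of the first (lower-mean) component.  Single-mode
#' models (typical of non-droplet platforms) are represented with `w = 1`
#' and both components equal.
#'
#' @param mu1,mu2 Component means (log2 reads).
#' @param sigma1,sigma2 Component standard deviations (log2 reads), > 0.
#' @param w Weight of the first component, in \[0, 1\].
#' @param ... Optional fit diagnostics (loglik, n_iter, converged, bic, n).
#' @return A `library_size_model` object.
#' @export
library_size_model <- function(mu1, sigma1, mu2, sigma2, w, ...) {
  mu1 <- unname(mu1); sigma1 <- unname(sigma1)
  mu2 <- unname(mu2); sigma2 <- unname(sigma2); w <- unname(w)
  stopifnot(is.finite(mu1), is.finite(mu2), sigma1 > 0, sigma2 > 0,
            w >= 0, w <= 1)
  if (mu1 > mu2) {  # canonicalize: first component has the lower mean
    tmp <- c(mu1, sigma1); mu1 <- mu2; sigma1 <- sigma2
    mu2 <- tmp[[1L]]; sigma2 <- tmp[[2L]]
    w <- 1 - w
  }
  structure(list(mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
                 w = w, ...),
            class = "library_size_model")
}

#' @export
print.library_size_model <- function(x, ...) {
  cat(sprintf(
    "library_size_model (log2 scale): %.3f * N(%.3f, %.3f^2) + %.3f * N(%.3f, %.3f^2)\n",
    x$w, x$mu1, x$sigma1, 1 - x$w, x$mu2, x$sigma2))
  invisible(x)
}

# log-sum-exp over the columns of a 2-column matrix
lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Fit the library-size Gaussian mixture by EM
#'
#' Fits a one- or two-component Gaussian mixture to log2-transformed
#' library sizes by expectation-maximization.  Responsibilities are
#' initialized by splitting the sorted values in half (lower half to
#' component 1); iteration stops when the log-likelihood changes by less
#' than `tol`.  Component variances are floored at `var_floor` to prevent
#' collapse on (near-)degenerate data.  With `n_components = 1` the second
#' component is reported equal to the first with `w = 1` — the convention
#' for platforms whose library sizes are unimodal.
#'
#' @param library_sizes Positive numeric vector of per-cell library sizes
#'   (raw scale; at least 10 values).
#' @param n_components 1 or 2.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param var_floor Lower bound on component variances (log2 scale).
#' @param seed Optional integer; the fit itself is deterministic, the seed
#'   is accepted for interface uniformity and recorded in the result.
#' @return A `library_size_model` with diagnostics `loglik`, `bic`,
#'   `n_iter`, `converged`, `n`.
#' @export
estimate_library_model <- function(library_sizes, n_components = 2,
                                   max_iter = 500L, tol = 1e-6,
                                   var_floor = 1e-6, seed = NULL) {
  x <- as.numeric(library_sizes)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("library sizes must be positive and finite ",
         "(drop zero-library cells before fitting)", call. = FALSE)
  }
  if (length(x) < 10L) {
    stop("need at least 10 cells to fit the library-size model, got ",
         length(x), call. = FALSE)
  }
  if (!n_components %in% c(1L, 2L)) {
    stop("n_components must be 1 or 2", call. = FALSE)
  }
  y <- log2(x)
  n <- length(y)

  if (n_components == 1L) {
    mu <- mean(y)
    s <- sqrt(max(stats::var(y), var_floor))
    ll <- sum(stats::dnorm(y, mu, s, log = TRUE))
    return(library_size_model(mu, s, mu, s, w = 1,
                              loglik = ll, bic = -2 * ll + 2 * log(n),
                              n_iter = 0L, converged = TRUE, n = n))
  }

  # initial hard assignment: lower half of the sorted values -> component 1
  r1 <- as.numeric(rank(y, ties.method = "first") <= n / 2)
  r <- cbind(r1, 1 - r1)
  mu <- c(0, 0); sg <- c(1, 1); w <- c(0.5, 0.5)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # M-step
    nk <- pmax(colSums(r), 1e-10)
    w <- nk / n
    mu <- colSums(r * y) / nk
    sg <- sqrt(pmax(colSums(r * (cbind(y, y) -
                                   rep(mu, each = n))^2) / nk, var_floor))
    # E-step
    la <- log(pmax(w[1L], 1e-300)) + stats::dnorm(y, mu[1L], sg[1L], log = TRUE)
    lb <- log(pmax(w[2L], 1e-300)) + stats::dnorm(y, mu[2L], sg[2L], log = TRUE)
    tot <- lse2(la, lb)
    r <- cbind(exp(la - tot), exp(lb - tot))
    ll <- sum(tot)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) {
      converged <- TRUE
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }
  if (!converged) {
    warning("library-size EM did not converge in ", max_iter,
            " iterations; returning best fit so far", call. = FALSE)
  }
  library_size_model(mu[1L], sg[1L], mu[2L], sg[2L], w = w[1L],
                     loglik = ll_prev, bic = -2 * ll_prev + 5 * log(n),
                     n_iter = iter, converged = converged, n = n)
}

#' Per-bin non-zero cell proportions
#'
#' For each bin j, the fraction of cells with at least one read in that
#' bin: `p_j = #\{i : M[j, i] > 0\} / C`.  This is the accessibility proxy
#' that drives both the Bernoulli sparsity mask and the bin-mean model.
#'
#' @param m A `bin_cell_matrix`.
#' @return Numeric vector of length B with values in \[0, 1\].
#' @export
estimate_nonzero_proportions <- function(m) {
  stopifnot(inherits(m, "bin_cell_matrix"))
  tabulate(m$counts@i + 1L, nbins = nrow(m$counts)) / ncol(m$counts)
}

#' Library-size normalization of a count matrix
#'
#' Divides each cell's counts by its library size and multiplies by the
#' median library size, so every column sums exactly to the median.  Bin
#' means of the result are comparable across cells with different depths.
#'
#' @param m A `bin_cell_matrix`; every cell must have library size > 0.
#' @return A real-valued sparse `dgCMatrix` of the same dimensions.
#' @export
normalize_matrix <- function(m) {
  stopifnot(inherits(m, "bin_cell_matrix"))
  lib <- Matrix::colSums(m$counts)
  if (any(lib == 0)) {
    stop(sum(lib == 0), " cell(s) have zero library size; ",
         "drop them before normalization", call. = FALSE)
  }
  med <- stats::median(lib)
  m$counts %*% Matrix::Diagonal(x = med / lib)
}

#' Quadratic fit of normalized bin means on non-zero proportions
#'
#' Ordinary least squares fit of `mean_j = beta0 + beta1 * p_j +
#' beta2 * p_j^2` over all bins, the empirical relationship linking a
#' bin's accessibility (non-zero cell proportion) to its average
#' normalized read count.
#'
#' @param p Non-zero cell proportions, length B >= 3, values in \[0, 1\].
#' @param normalized_bin_means Row means of the normalized matrix, length B.
#' @return List with `beta0`, `beta1`, `beta2`, `residual_sd`, `r_squared`.
#' @export
fit_bin_mean_polynomial <- function(p, normalized_bin_means) {
  p <- as.numeric(p)
  y <- as.numeric(normalized_bin_means)
  if (length(p) != length(y)) {
    stop("p and normalized_bin_means must have the same length", call. = FALSE)
  }
  if (length(p) < 3L) stop("need at least 3 bins", call. = FALSE)
  if (any(p < 0) || any(p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (length(unique(p)) < 3L) {
    stop("degenerate input: need at least 3 distinct non-zero proportions ",
         "to fit a quadratic", call. = FALSE)
  }
  fit <- stats::lm(y ~ p + I(p^2))
  cf <- unname(stats::coef(fit))
  res <- stats::residuals(fit)
  tss <- sum((y - mean(y))^2)
  list(beta0 = cf[[1L]], beta1 = cf[[2L]], beta2 = cf[[3L]],
       residual_sd = sqrt(sum(res^2) / max(1, length(y) - 3)),
       r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_)
}

#' Per-bin model parameters
#'
#' @param p Non-zero cell proportions (length B, in \[0, 1\]).
#' @param beta0,beta1,beta2 Quadratic bin-mean coefficients.
#' @param median_library_size Median library size of the source cells
#'   (normalization anchor), > 0.
#' @return A `bin_model` object.
#' @export
bin_model <- function(p, beta0, beta1, beta2, median_library_size) {
  p <- as.numeric(p)
  stopifnot(length(p) > 0, all(p >= 0), all(p <= 1),
            is.finite(beta0), is.finite(beta1), is.finite(beta2),
            median_library_size > 0)
  structure(list(p = p, beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 median_library_size = median_library_size),
            class = "bin_model")
}

#' Simulation profile
#'
#' The complete set of estimated parameters needed to simulate a cell
#' group: the library-size mixture, the per-bin model, and the bin space.
#'
#' @param library_model A `library_size_model`.
#' @param bin_model A `bin_model` whose `p` has one entry per bin.
#' @param bins A `genome_bins` object.
#' @param n_cells_source Number of cells the profile was estimated from.
#' @param group_label Optional group label.
#' @return A `simulation_profile` object.
#' @export
simulation_profile <- function(library_model, bin_model, bins,
                               n_cells_source = NA_integer_,
                               group_label = NULL) {
  stopifnot(inherits(library_model, "library_size_model"),
            inherits(bin_model, "bin_model"),
            inherits(bins, "genome_bins"))
  if (length(bin_model$p) != nrow(bins)) {
    stop("bin_model has ", length(bin_model$p), " proportions but the bin ",
         "space has ", nrow(bins), " bins", call. = FALSE)
  }
  structure(list(library_model = library_model, bin_model = bin_model,
                 bins = bins, n_cells_source = n_cells_source,
                 group_label = group_label),
            class = "simulation_profile")
}

#' @export
print.simulation_profile <- function(x, ...) {
  cat(sprintf("simulation_profile: %d bins, estimated from %s cells%s\n",
              nrow(x$bins), x$n_cells_source,
              if (is.null(x$group_label)) "" else paste0(" (", x$group_label, ")")))
  print(x$library_model)
  cat(sprintf("bin model: beta = (%.4g, %.4g, %.4g), median library size %.1f\n",
              x$bin_model$beta0, x$bin_model$beta1, x$bin_model$beta2,
              x$bin_model$median_library_size))
  invisible(x)
}

#' Estimate a simulation profile from a real bin-by-cell matrix
#'
#' Composes the three estimators: (i) the library-size Gaussian mixture on
#' log2 column sums, (ii) per-bin non-zero cell proportions, and (iii) the
#' quadratic regression of normalized bin means on those proportions.
#' Cells with zero library size are dropped with a warning before any
#' estimation.
#'
#' @param m A `bin_cell_matrix` for one cell group.
#' @param platform_hint `"bimodal"` (droplet-style platforms; two mixture
#'   components, the default), `"unimodal"` (single component, `w = 1`),
#'   or `"auto"` (fit both, choose by BIC).
#' @param seed Optional integer recorded with the fit.
#' @return A `simulation_profile`.
#' @export
estimate_profile <- function(m, platform_hint = c("bimodal", "unimodal", "auto"),
                             seed = NULL) {
  stopifnot(inherits(m, "bin_cell_matrix"))
  platform_hint <- match.arg(platform_hint)
  lib <- Matrix::colSums(m$counts)
  keep <- lib > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " cell(s) with zero library size",
            call. = FALSE)
    m <- bin_cell_matrix(m$counts[, keep, drop = FALSE], m$bins,
                         m$barcodes[keep], group_label = m$group_label)
    lib <- lib[keep]
  }
  lm_fit <- switch(platform_hint,
    bimodal  = estimate_library_model(lib, n_components = 2L, seed = seed),
    unimodal = estimate_library_model(lib, n_components = 1L, seed = seed),
    auto = {
      f1 <- estimate_library_model(lib, n_components = 1L, seed = seed)
      f2 <- estimate_library_model(lib, n_components = 2L, seed = seed)
      if (f1$bic <= f2$bic) f1 else f2
    })
  p <- estimate_nonzero_proportions(m)
  norm <- normalize_matrix(m)
  nbm <- Matrix::rowMeans(norm)
  beta <- fit_bin_mean_polynomial(p, nbm)
  simulation_profile(
    library_model = lm_fit,
    bin_model = bin_model(p, beta$beta0, beta$beta1, beta$beta2,
                          median_library_size = stats::median(lib)),
    bins = m$bins,
    n_cells_source = ncol(m$counts),
    group_label = m$group_label
  )
}

#' Serialize a simulation profile to a directory
#'
#' Writes `profile.json` (scalar parameters), `p.tsv` (one non-zero
#' proportion per bin) and `bins.bed`.  [read_profile()] inverts this.
#'
#' @param profile A `simulation_profile`.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, `out_dir`.
#' @export
write_profile <- function(profile, out_dir) {
  stopifnot(inherits(profile, "simulation_profile"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lm <- profile$library_model
  bm <- profile$bin_model
  scalars <- list(
    mu1 = lm$mu1, sigma1 = lm$sigma1, mu2 = lm$mu2, sigma2 = lm$sigma2,
    w = lm$w,
    beta0 = bm$beta0, beta1 = bm$beta1, beta2 = bm$beta2,
    median_library_size = bm$median_library_size,
    n_cells_source = profile$n_cells_source,
    group_label = profile$group_label %||% NA
  )
  jsonlite::write_json(scalars, file.path(out_dir, "profile.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(formatC(bm$p, digits = 17, format = "g"),
             file.path(out_dir, "p.tsv"))
  write_bins_bed(profile$bins, file.path(out_dir, "bins.bed"))
  invisible(out_dir)
}

#' Read a simulation profile from a directory
#'
#' @param dir Directory written by [write_profile()].
#' @return A `simulation_profile`.
#' @export
read_profile <- function(dir) {
  pj <- file.path(dir, "profile.json")
  if (!file.exists(pj)) stop("no profile.json in ", dir, call. = FALSE)
  s <- jsonlite::read_json(pj, simplifyVector = TRUE)
  p <- utils::read.table(file.path(dir, "p.tsv"), header = FALSE)[[1L]]
  bins <- read_bins_bed(file.path(dir, "bins.bed"))
  gl <- s$group_label
  if (is.null(gl) || (length(gl) == 1L && is.na(gl))) gl <- NULL
  simulation_profile(
    library_size_model(s$mu1, s$sigma1, s$mu2, s$sigma2, s$w),
    bin_model(p, s$beta0, s$beta1, s$beta2, s$median_library_size),
    bins,
    n_cells_source = s$n_cells_source %||% NA_integer_,
    group_label = gl
  )
}
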