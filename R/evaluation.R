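#' Elementwise deviation metrics between paired vectors
#'
#' `err_mad(R, S) = median(|R - S|)`, `err_mae(R, S) = mean(|R - S|)`,
#' `err_rmse(R, S) = sqrt(mean((R - S)^2))` — the three resemblance
#' metrics used to compare real and simulated summary vectors (sorted
#' library sizes, bin means, non-zero cell proportions).  For even-length
#' vectors the median is the mean of the two central order statistics.
#'
#' @param R,S Numeric vectors of equal length (R real, S simulated).
#' @return A single non-negative number.
#' @export
err_mad <- function(R, S) stats::median(abs(check_pair(R, S)))

#' @rdname err_mad
#' @export
err_mae <- function(R, S) mean(abs(check_pair(R, S)))

#' @rdname err_mad
#' @export
err_rmse <- function(R, S) sqrt(mean(check_pair(R, S)^2))

check_pair <- function(R, S) {
  if (length(R) != length(S)) {
    stop("R and S must have the same length (", length(R), " vs ",
         length(S), ")", call. = FALSE)
  }
  if (length(R) < 1L) stop("vectors must be non-empty", call. = FALSE)
  as.numeric(R) - as.numeric(S)
}

# ---- clustering agreement scores --------------------------------------

label_table <- function(gt, pred) {
  if (length(gt) != length(pred)) {
    stop("gt and pred must have the same length", call. = FALSE)
  }
  if (length(gt) < 1L) stop("labelings must be non-empty", call. = FALSE)
  table(factor(gt), factor(pred))
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

mi_from_table <- function(tab) {
  N <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  nz <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[nz]
  sum(nij / N * log(N * nij / (a[nz[, 1L]] * b[nz[, 2L]])))
}

# exact expected mutual information under the permutation model: each
# contingency cell count follows a hypergeometric distribution
expected_mi <- function(a, b, N) {
  total <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      lw <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) +
        lgamma(N - bj + 1) - lgamma(N + 1) - lgamma(nij + 1) -
        lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
        lgamma(N - ai - bj + nij + 1)
      total <- total + sum(nij / N * log(N * nij / (ai * bj)) * exp(lw))
    }
  }
  total
}

# TRUE when the two labelings induce exactly the same partition
same_partition <- function(tab) {
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

#' Normalized mutual information
#'
#' `NMI = MI(gt, pred) / max(H(gt), H(pred))` with natural-log plug-in
#' entropies.  When both labelings are constant the limit is defined as 1;
#' when exactly one is constant, 0.
#'
#' @param gt,pred Label vectors of equal length (any atomic type).
#' @return A number in \[0, 1\].
#' @export
nmi <- function(gt, pred) {
  tab <- label_table(gt, pred)
  hg <- entropy_counts(rowSums(tab))
  hp <- entropy_counts(colSums(tab))
  if (hg == 0 && hp == 0) return(1)
  if (hg == 0 || hp == 0) return(0)
  mi_from_table(tab) / max(hg, hp)
}

#' Adjusted mutual information
#'
#' `AMI = (MI - E[MI]) / (mean(H(gt), H(pred)) - E[MI])`, where `E[MI]` is
#' the exact expected mutual information under random permutation of the
#' labels (hypergeometric model) and the denominator uses the arithmetic
#' mean of the two entropies.  Chance-level agreement scores near 0;
#' identical partitions score 1.
#'
#' @inheritParams nmi
#' @return A number `<= 1` (can be negative for worse-than-chance
#'   agreement).
#' @export
ami <- function(gt, pred) {
  tab <- label_table(gt, pred)
  N <- sum(tab)
  hg <- entropy_counts(rowSums(tab))
  hp <- entropy_counts(colSums(tab))
  emi <- expected_mi(rowSums(tab), colSums(tab), N)
  denom <- (hg + hp) / 2 - emi
  mi <- mi_from_table(tab)
  if (abs(denom) < 1e-12) {
    return(if (same_partition(tab)) 1 else 0)
  }
  (mi - emi) / denom
}

#' Adjusted Rand index
#'
#' Pair-counting agreement corrected for chance:
#' `ARI = (RI - E[RI]) / (max(RI) - E[RI])` computed via the standard
#' contingency-table identity over all pairs of items.
#'
#' @inheritParams nmi
#' @return A number `<= 1`; 0 expected for random labelings.
#' @export
ari <- function(gt, pred) {
  tab <- label_table(gt, pred)
  N <- sum(tab)
  if (N < 2) stop("need at least 2 items for ARI", call. = FALSE)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(N, 2)
  expected <- sum_a * sum_b / tot
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < 1e-12) {
    return(if (same_partition(tab)) 1 else 0)
  }
  (sum_ij - expected) / (maximum - expected)
}

#' Cluster agreement report
#'
#' Convenience wrapper computing all three scores at once.
#'
#' @inheritParams nmi
#' @return List with `nmi`, `ami`, `ari`.
#' @export
score_clusters <- function(gt, pred) {
  list(nmi = nmi(gt, pred), ami = ami(gt, pred), ari = ari(gt, pred))
}

# ---- matrix-level resemblance -----------------------------------------

matrix_summaries <- function(m) {
  list(lib = sort(Matrix::colSums(m$counts)),
       bin_means = Matrix::rowSums(m$counts) / ncol(m$counts),
       p = estimate_nonzero_proportions(m))
}

#' Compare a simulated matrix (or simulator) against a real matrix
#'
#' Computes MAD / MAE / RMSE between real and simulated sorted library
#' sizes, bin means, and per-bin non-zero cell proportions, plus Pearson
#' correlations of the two bin-wise summaries.  Library sizes are compared
#' as sorted vectors (distribution-level comparison); when the two
#' matrices have different cell counts the simulated sorted vector is
#' mapped onto the real one's length by quantile interpolation and the
#' report flags this.  Supplying `simulate_fn` repeats the simulation
#' `n_runs` times (seeded `seed, seed + 1, ...`) and reports
#' mean and standard deviation of every metric across runs.
#'
#' @param real A `bin_cell_matrix` (the reference).
#' @param sim A `bin_cell_matrix`, or NULL when `simulate_fn` is given.
#' @param n_runs Number of simulation runs to average over.
#' @param simulate_fn Function taking one integer seed and returning a
#'   `bin_cell_matrix` on the same bin space as `real`.
#' @param seed Base seed for `simulate_fn` runs.
#' @return A `resemblance_report`: per-quantity mean and sd of each
#'   metric, `pearson_bin_mean`, `pearson_nonzero_prop`, `n_runs`,
#'   `resampled`, and the per-run table.
#' @export
compare_matrices <- function(real, sim = NULL, n_runs = 1L,
                             simulate_fn = NULL, seed = 1L) {
  stopifnot(inherits(real, "bin_cell_matrix"))
  if (is.null(sim) && is.null(simulate_fn)) {
    stop("supply either sim or simulate_fn", call. = FALSE)
  }
  if (is.null(simulate_fn)) n_runs <- 1L
  rs <- matrix_summaries(real)
  B <- nrow(real$counts)
  rows <- vector("list", n_runs)
  resampled <- FALSE
  for (r in seq_len(n_runs)) {
    s <- if (is.null(simulate_fn)) sim else simulate_fn(as.integer(seed) + r - 1L)
    stopifnot(inherits(s, "bin_cell_matrix"))
    if (nrow(s$counts) != B) {
      stop("matrices are on different bin spaces (", B, " vs ",
           nrow(s$counts), " bins)", call. = FALSE)
    }
    ss <- matrix_summaries(s)
    slib <- ss$lib
    if (length(slib) != length(rs$lib)) {
      resampled <- TRUE
      slib <- stats::approx(x = seq(0, 1, length.out = length(slib)),
                            y = slib,
                            xout = seq(0, 1, length.out = length(rs$lib)))$y
    }
    rows[[r]] <- data.frame(
      run = r,
      lib_mad = err_mad(rs$lib, slib),
      lib_mae = err_mae(rs$lib, slib),
      lib_rmse = err_rmse(rs$lib, slib),
      bin_mean_mad = err_mad(rs$bin_means, ss$bin_means),
      bin_mean_mae = err_mae(rs$bin_means, ss$bin_means),
      bin_mean_rmse = err_rmse(rs$bin_means, ss$bin_means),
      nzp_mad = err_mad(rs$p, ss$p),
      nzp_mae = err_mae(rs$p, ss$p),
      nzp_rmse = err_rmse(rs$p, ss$p),
      pearson_bin_mean = stats::cor(rs$bin_means, ss$bin_means),
      pearson_nonzero_prop = stats::cor(rs$p, ss$p)
    )
  }
  per_run <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_run), "run")
  structure(list(
    mean = vapply(per_run[metric_cols], mean, numeric(1)),
    sd = vapply(per_run[metric_cols], stats::sd, numeric(1)),
    pearson_bin_mean = mean(per_run$pearson_bin_mean),
    pearson_nonzero_prop = mean(per_run$pearson_nonzero_prop),
    n_runs = n_runs,
    resampled = resampled,
    per_run = per_run
  ), class = "resemblance_report")
}

#' @export
print.resemblance_report <- function(x, ...) {
  cat(sprintf("resemblance_report over %d run(s)%s\n", x$n_runs,
              if (x$resampled) " (library sizes quantile-resampled)" else ""))
  m <- rbind(
    `sorted library size` = x$mean[c("lib_mad", "lib_mae", "lib_rmse")],
    `bin mean` = x$mean[c("bin_mean_mad", "bin_mean_mae", "bin_mean_rmse")],
    `non-zero proportion` = x$mean[c("nzp_mad", "nzp_mae", "nzp_rmse")])
  colnames(m) <- c("MAD", "MAE", "RMSE")
  print(signif(m, 4))
  cat(sprintf("Pearson r: bin means %.4f, non-zero proportions %.4f\n",
              x$pearson_bin_mean, x$pearson_nonzero_prop))
  invisible(x)
}

#' Bin-sparsity quantile-quantile table
#'
#' Reduces the per-bin zero fractions of two matrices on the same bin
#' space to matched quantiles, for QQ plotting or export.  Identical
#' matrices produce points exactly on the diagonal.
#'
#' @param real,sim `bin_cell_matrix` objects with equal bin counts.
#' @param n_quantiles Number of evenly spaced probabilities in \[0, 1\]
#'   (>= 2; 2 gives just min and max).
#' @return data.frame with columns `prob`, `real`, `sim`.
#' @export
bin_sparsity_qq <- function(real, sim, n_quantiles = 101L) {
  stopifnot(inherits(real, "bin_cell_matrix"), inherits(sim, "bin_cell_matrix"))
  if (nrow(real$counts) != nrow(sim$counts)) {
    stop("matrices are on different bin spaces", call. = FALSE)
  }
  if (n_quantiles < 2L) stop("n_quantiles must be >= 2", call. = FALSE)
  zr <- 1 - tabulate(real$counts@i + 1L, nrow(real$counts)) / ncol(real$counts)
  zs <- 1 - tabulate(sim$counts@i + 1L, nrow(sim$counts)) / ncol(sim$counts)
  probs <- seq(0, 1, length.out = n_quantiles)
  data.frame(prob = probs,
             real = unname(stats::quantile(zr, probs)),
             sim = unname(stats::quantile(zs, probs)))
}
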