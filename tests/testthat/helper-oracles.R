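# Independent oracle implementations used to check the package's fast
# paths.  These deliberately use different algorithms (naive loops,
# dhyper-based expectations, pair enumeration, quadratic scans) from the
# implementations they verify.

oracle_entropy <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  -sum(p * log(p))
}

oracle_mi <- function(gt, pred) {
  n <- length(gt)
  total <- 0
  for (g in unique(gt)) {
    for (q in unique(pred)) {
      nij <- sum(gt == g & pred == q)
      if (nij == 0) next
      pij <- nij / n
      total <- total + pij * log(pij / ((sum(gt == g) / n) * (sum(pred == q) / n)))
    }
  }
  total
}

oracle_nmi <- function(gt, pred) {
  hg <- oracle_entropy(gt); hp <- oracle_entropy(pred)
  if (hg == 0 && hp == 0) return(1)
  if (hg == 0 || hp == 0) return(0)
  oracle_mi(gt, pred) / max(hg, hp)
}

# expected MI under the permutation null, with hypergeometric weights
# taken from stats::dhyper rather than explicit lgamma sums
oracle_emi <- function(gt, pred) {
  n <- length(gt)
  a <- as.numeric(table(gt)); b <- as.numeric(table(pred))
  total <- 0
  for (ai in a) {
    for (bj in b) {
      for (nij in max(1, ai + bj - n):min(ai, bj)) {
        if (nij < 1) next
        w <- stats::dhyper(nij, ai, n - ai, bj)
        total <- total + w * nij / n * log(n * nij / (ai * bj))
      }
    }
  }
  total
}

oracle_ami <- function(gt, pred) {
  emi <- oracle_emi(gt, pred)
  denom <- (oracle_entropy(gt) + oracle_entropy(pred)) / 2 - emi
  (oracle_mi(gt, pred) - emi) / denom
}

# ARI by explicit enumeration of all n(n-1)/2 item pairs
oracle_ari <- function(gt, pred) {
  n <- length(gt)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sg <- gt[i] == gt[j]; sp <- pred[i] == pred[j]
      if (sg && sp) a <- a + 1
      else if (sg && !sp) b <- b + 1
      else if (!sg && sp) cc <- cc + 1
      else d <- d + 1
    }
  }
  den <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (den == 0) return(1)
  2 * (a * d - b * cc) / den
}

# brute-force top-k bin selection by mean, ties to the lower index
oracle_topk <- function(counts, k) {
  means <- rowSums(as.matrix(counts)) / ncol(counts)
  ord <- order(-means, seq_along(means))
  sort(ord[seq_len(k)])
}

# quadratic scan: per-region counts as explicit bin-by-bin overlap sums
oracle_region_counts <- function(m, regions) {
  dense <- as.matrix(m$counts)
  out <- matrix(0, nrow(regions), ncol(dense))
  for (r in seq_len(nrow(regions))) {
    for (b in seq_len(nrow(m$bins))) {
      if (m$bins$chrom[b] == regions$chrom[r] &&
          m$bins$start[b] < regions$end[r] &&
          m$bins$end[b] > regions$start[r]) {
        out[r, ] <- out[r, ] + dense[b, ]
      }
    }
  }
  out
}

rand_labels <- function(n, k) sample.int(k, n, replace = TRUE)
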