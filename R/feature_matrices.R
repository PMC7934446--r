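#' Read a BED file of regions
#'
#' Unlike [read_bins_bed()], regions may overlap each other and need not
#' tile the genome; only `start < end` is enforced.
#'
#' @param path BED3 (or wider) file, 0-based half-open.
#' @return A `region_set` data.frame with columns `chrom`, `start`, `end`
#'   (and `name` when a fourth column is present).
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file must have at least 3 columns", call. = FALSE)
  region_set(df[[1L]], as.numeric(df[[2L]]), as.numeric(df[[3L]]),
             name = if (ncol(df) >= 4L) as.character(df[[4L]]) else NULL)
}

#' Construct a region set
#'
#' @param chrom,start,end Parallel coordinate vectors (0-based half-open).
#' @param name Optional region names.
#' @return A `region_set` data.frame.
#' @export
region_set <- function(chrom, start, end, name = NULL) {
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(out$start < 0) || any(out$end <= out$start)) {
    stop("regions must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!is.null(name)) out$name <- name
  class(out) <- c("region_set", "data.frame")
  out
}

#' Peak-by-cell matrix: top bins by mean count
#'
#' Ranks bins by mean count across cells (row sum / C) in descending
#' order, breaking ties by ascending bin index, and keeps the top
#' `n_peaks` rows.  The retained bins — a stand-in for called peaks, the
#' read-enriched regions — are returned in genomic order, with the rank
#' of each kept bin attached as metadata.
#'
#' @param m A `bin_cell_matrix`.
#' @param n_peaks Number of bins to keep, between 1 and B.
#' @return A `bin_cell_matrix` with `n_peaks` rows; attribute `peak_rank`
#'   gives each retained row's enrichment rank (1 = highest mean).
#' @export
get_peak_by_cell <- function(m, n_peaks) {
  stopifnot(inherits(m, "bin_cell_matrix"))
  n_peaks <- as.integer(n_peaks)
  B <- nrow(m$counts)
  if (is.na(n_peaks) || n_peaks < 1L || n_peaks > B) {
    stop("n_peaks must be between 1 and ", B, call. = FALSE)
  }
  means <- Matrix::rowSums(m$counts) / ncol(m$counts)
  ranking <- order(-means, seq_len(B))       # ties: ascending bin index
  keep <- sort(ranking[seq_len(n_peaks)])    # back to genomic order
  bins <- genome_bins(m$bins$chrom[keep], m$bins$start[keep],
                      m$bins$end[keep],
                      bin_width = attr(m$bins, "bin_width"))
  out <- bin_cell_matrix(m$counts[keep, , drop = FALSE], bins, m$barcodes,
                         group_label = m$group_label)
  attr(out, "peak_rank") <- match(keep, ranking)
  out
}

#' Region-by-cell feature matrix
#'
#' Aggregates bin counts into user-supplied regions: the count for
#' (region, cell) is the sum of that cell's counts over every bin
#' overlapping the region by at least 1 bp (unweighted; a bin shared by
#' two regions is counted fully in both).  Regions on chromosomes absent
#' from the bin space produce all-zero rows with a warning.
#'
#' @param m A `bin_cell_matrix`.
#' @param features A `region_set` (see [read_regions_bed()]).
#' @return List with `counts` (sparse regions x cells matrix), `regions`
#'   (the input `region_set`), `barcodes`.
#' @export
get_feature_by_cell <- function(m, features) {
  stopifnot(inherits(m, "bin_cell_matrix"), inherits(features, "region_set"))
  missing_chr <- setdiff(unique(features$chrom), unique(m$bins$chrom))
  if (length(missing_chr)) {
    warning("region chromosome(s) absent from the bin space (rows will be ",
            "zero): ", paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    bins_as_granges(features), bins_as_granges(m$bins), minoverlap = 1L))
  # indicator matrix A (regions x bins); counts = A %*% M
  A <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                            j = S4Vectors::subjectHits(hits),
                            x = 1,
                            dims = c(nrow(features), nrow(m$bins)))
  list(counts = as_dgc(A %*% m$counts),
       regions = features,
       barcodes = m$barcodes)
}

#' Binary accessibility matrix
#'
#' Replaces every positive count by 1; dimensions, bins and barcodes are
#' preserved.  Idempotent.
#'
#' @param m A `bin_cell_matrix`.
#' @return A `bin_cell_matrix` of 0/1 values.
#' @export
get_binary <- function(m) {
  stopifnot(inherits(m, "bin_cell_matrix"))
  b <- m$counts
  b@x <- rep.int(1, length(b@x))
  bin_cell_matrix(b, m$bins, m$barcodes, group_label = m$group_label)
}
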