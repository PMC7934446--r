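#' Read a UCSC-style chrom.sizes file
#'
#' Parses a two-column whitespace-delimited file of chromosome names and
#' lengths (the UCSC `chrom.sizes` dialect).  Row order is preserved: it
#' defines the chromosome order of every bin space built from the result.
#'
#' @param path Path to a two-column file (name, length in bp).
#' @return A `chrom_sizes` object: a data.frame with columns `chrom`
#'   (character) and `length` (integer bp), one row per chromosome, in file
#'   order.
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t248956422", "chrM\t16569"), f)
#' read_chrom_sizes(f)
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) {
    stop("chrom.sizes file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("chrom.sizes file is empty: ", path, call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  chrom <- character(length(fields))
  len <- integer(length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 2L) {
      stop("malformed chrom.sizes row at line ", k, ": ", lines[[k]],
           call. = FALSE)
    }
    n <- suppressWarnings(as.numeric(f[[2L]]))
    if (is.na(n) || n != round(n)) {
      stop("non-integer chromosome length at line ", k, ": ", f[[2L]],
           call. = FALSE)
    }
    if (n <= 0) {
      stop("non-positive chromosome length at line ", k, ": ", f[[2L]],
           call. = FALSE)
    }
    chrom[[k]] <- f[[1L]]
    len[[k]] <- as.integer(n)
  }
  dup <- anyDuplicated(chrom)
  if (dup) {
    stop("duplicate chromosome name at line ", dup, ": ", chrom[[dup]],
         call. = FALSE)
  }
  chrom_sizes(chrom, len)
}

#' Construct a chrom_sizes object
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of positive lengths (bp), same order.
#' @return A `chrom_sizes` data.frame.
#' @export
chrom_sizes <- function(chrom, length) {
  stopifnot(length(chrom) == length(length))
  if (anyDuplicated(chrom)) stop("chromosome names must be unique", call. = FALSE)
  if (any(length < 1)) stop("chromosome lengths must be >= 1", call. = FALSE)
  out <- data.frame(chrom = as.character(chrom),
                    length = as.integer(length),
                    stringsAsFactors = FALSE)
  class(out) <- c("chrom_sizes", "data.frame")
  out
}

#' Tile a genome into fixed-width bins
#'
#' Segments every chromosome into contiguous, non-overlapping windows of
#' `bin_width` bp (default 5000, the 5-kbp convention for chromatin
#' accessibility bin-by-cell matrices).  The last bin of each chromosome is
#' truncated so that bins exactly cover `[0, length)`; at 5 kbp the human
#' genome (canonical chromosomes) yields on the order of 600,000 bins.
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param sizes A `chrom_sizes` object (see [read_chrom_sizes()]).
#' @param bin_width Positive integer window width in bp.
#' @return A `genome_bins` object: a data.frame with columns `chrom`,
#'   `start`, `end` and attribute `bin_width`.  Chromosomes appear in
#'   `sizes` order; bins within a chromosome are sorted by start.
#' @export
make_bins <- function(sizes, bin_width = 5000L) {
  stopifnot(inherits(sizes, "chrom_sizes") || is.data.frame(sizes))
  if (nrow(sizes) == 0L) stop("empty chrom_sizes", call. = FALSE)
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width < 1L) {
    stop("bin_width must be a positive integer", call. = FALSE)
  }
  n_per <- as.integer(ceiling(sizes$length / bin_width))
  chrom <- rep.int(sizes$chrom, n_per)
  # bin k on a chromosome is [k*w, min((k+1)*w, L)); doubles avoid int overflow
  k <- unlist(lapply(n_per, function(n) seq_len(n) - 1), use.names = FALSE)
  w <- as.numeric(bin_width)
  start <- k * w
  end <- pmin(start + w, rep.int(as.numeric(sizes$length), n_per))
  genome_bins(chrom, start, end, bin_width = bin_width)
}

#' Construct and validate a genome_bins object
#'
#' @param chrom,start,end Parallel vectors of bin coordinates (0-based
#'   half-open).
#' @param bin_width Nominal bin width; inferred as the maximum bin width when
#'   missing.
#' @return A `genome_bins` data.frame.
#' @export
genome_bins <- function(chrom, start, end, bin_width = NULL) {
  out <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start),
                    end = as.numeric(end),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("bin set must be non-empty", call. = FALSE)
  if (any(out$start < 0) || any(out$end <= out$start)) {
    stop("bins must satisfy 0 <= start < end", call. = FALSE)
  }
  widths <- out$end - out$start
  if (is.null(bin_width)) bin_width <- max(widths)
  if (any(widths > bin_width)) {
    stop("bins wider than bin_width ", bin_width, call. = FALSE)
  }
  # per chromosome: sorted and non-overlapping; gaps are allowed so that
  # row subsets (e.g. peak selections) remain valid bin annotations
  for (ch in unique(out$chrom)) {
    b <- out[out$chrom == ch, , drop = FALSE]
    if (is.unsorted(b$start, strictly = TRUE)) {
      stop("bins on ", ch, " are not sorted by start", call. = FALSE)
    }
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)])) {
      stop("bins on ", ch, " overlap", call. = FALSE)
    }
  }
  attr(out, "bin_width") <- as.integer(bin_width)
  class(out) <- c("genome_bins", "data.frame")
  out
}

#' @export
print.genome_bins <- function(x, ...) {
  cat(sprintf("genome_bins: %d bins, %d chromosome(s), bin_width %d bp\n",
              nrow(x), length(unique(x$chrom)), attr(x, "bin_width")))
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' Write genome bins as BED3
#'
#' @param bins A `genome_bins` object.
#' @param path Output path; tab-delimited BED3, no header.
#' @export
write_bins_bed <- function(bins, path) {
  stopifnot(inherits(bins, "genome_bins"))
  df <- data.frame(bins$chrom,
                   format(bins$start, scientific = FALSE, trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read genome bins from a BED file
#'
#' Reads a 3+-column BED file and validates the bin-space invariants
#' (sorted, contiguous, non-overlapping, uniform width except the last bin
#' per chromosome).  `write_bins_bed()` followed by `read_bins_bed()` is the
#' identity.
#'
#' @param path Path to a BED3 (or wider) file.
#' @return A `genome_bins` object.
#' @export
read_bins_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file must have at least 3 columns", call. = FALSE)
  genome_bins(df[[1L]], as.numeric(df[[2L]]), as.numeric(df[[3L]]))
}

# GRanges view of a bin or region data.frame (1-based closed internally)
bins_as_granges <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end)
  )
}
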