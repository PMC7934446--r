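#' Construct a bin-by-cell count matrix
#'
#' Bundles a sparse non-negative integer count matrix (rows = genomic bins,
#' columns = cells) with its bin coordinates and cell barcodes.  Entry
#' (j, i) is the number of reads falling in bin j of cell i.
#'
#' @param counts A B x C matrix of non-negative integers; coerced to a
#'   `dgCMatrix`.
#' @param bins A `genome_bins` object with B bins.
#' @param barcodes Character vector of C unique cell identifiers.
#' @param group_label Optional cell type / group label.
#' @return A `bin_cell_matrix` object (list with elements `counts`, `bins`,
#'   `barcodes`, `group_label`).
#' @export
bin_cell_matrix <- function(counts, bins, barcodes, group_label = NULL) {
  counts <- as_dgc(counts)
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(inherits(bins, "genome_bins"))
  barcodes <- as.character(barcodes)
  if (nrow(counts) != nrow(bins)) {
    stop("count matrix has ", nrow(counts), " rows but bin set has ",
         nrow(bins), " bins", call. = FALSE)
  }
  if (ncol(counts) != length(barcodes)) {
    stop("count matrix has ", ncol(counts), " columns but ", length(barcodes),
         " barcodes were supplied", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("cell barcodes must be unique", call. = FALSE)
  }
  structure(list(counts = counts, bins = bins, barcodes = barcodes,
                 group_label = group_label),
            class = "bin_cell_matrix")
}

#' @export
print.bin_cell_matrix <- function(x, ...) {
  nz <- length(x$counts@x)
  cat(sprintf(
    "bin_cell_matrix: %d bins x %d cells, %d stored entries (%.1f%% dense)%s\n",
    nrow(x$counts), ncol(x$counts), nz,
    100 * nz / (as.numeric(nrow(x$counts)) * ncol(x$counts)),
    if (is.null(x$group_label)) "" else paste0(", group ", x$group_label)))
  invisible(x)
}

#' @export
dim.bin_cell_matrix <- function(x) dim(x$counts)

#' Read a sparse bin-by-cell matrix with its sidecars
#'
#' Loads the exchange triplet: a Matrix Market coordinate file, a BED3 file
#' of bin coordinates (rows), and a one-barcode-per-line TSV (columns).
#' Duplicate stored triplets in the mtx file are summed, with a warning.
#'
#' @param mtx_path Matrix Market coordinate file (integer or real entries,
#'   all values non-negative integers).
#' @param bins_bed_path BED3 file of the bin space, one row per matrix row.
#' @param barcodes_path One cell barcode per line, one per matrix column.
#' @param group_label Optional group label to attach.
#' @return A `bin_cell_matrix`.
#' @export
read_matrix <- function(mtx_path, bins_bed_path, barcodes_path,
                        group_label = NULL) {
  m <- Matrix::readMM(mtx_path)
  m <- methods::as(m, "TsparseMatrix")
  if (anyDuplicated(cbind(m@i, m@j))) {
    warning("duplicate triplets in ", mtx_path, "; summing", call. = FALSE)
  }
  m <- methods::as(m, "CsparseMatrix")  # sums duplicates
  bins <- read_bins_bed(bins_bed_path)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != nrow(bins)) {
    stop("mtx declares ", nrow(m), " rows but BED sidecar has ", nrow(bins),
         " bins", call. = FALSE)
  }
  if (ncol(m) != length(barcodes)) {
    stop("mtx declares ", ncol(m), " columns but barcode sidecar has ",
         length(barcodes), " entries", call. = FALSE)
  }
  bin_cell_matrix(m, bins, barcodes, group_label = group_label)
}

# Matrix Market "coordinate integer general" writer.  Matrix::writeMM only
# emits real-typed headers, so the triplets are formatted directly; entries
# are written in column-major order (the canonical dgCMatrix order).
write_mm_integer <- function(m, path) {
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  i <- m@i + 1L
  p <- m@p
  j <- rep.int(seq_len(ncol(m)), diff(p))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(i))), con)
  if (length(i)) {
    writeLines(sprintf("%d %d %d", i, j, as.integer(m@x)), con)
  }
  invisible(NULL)
}

#' Write a bin-by-cell matrix as an exchange triplet
#'
#' Writes `matrix.mtx` (Matrix Market coordinate integer), `bins.bed`
#' (BED3) and `barcodes.tsv` into `out_dir`.  [read_matrix()] on the three
#' files reproduces the object exactly.
#'
#' @param m A `bin_cell_matrix`.
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, the three file paths.
#' @export
write_matrix <- function(m, out_dir) {
  stopifnot(inherits(m, "bin_cell_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- file.path(out_dir, c("matrix.mtx", "bins.bed", "barcodes.tsv"))
  write_mm_integer(m$counts, paths[[1L]])
  write_bins_bed(m$bins, paths[[2L]])
  writeLines(m$barcodes, paths[[3L]])
  invisible(paths)
}

#' Per-cell summary: library sizes and sparsity
#'
#' Library size is the column sum (total aligned reads of a cell); cell
#' sparsity is the fraction of bins with zero count in that cell.  Cells
#' with library size 0 are flagged so callers can drop them before model
#' estimation.
#'
#' @param m A `bin_cell_matrix`.
#' @return A data.frame with columns `barcode`, `library_size`,
#'   `sparsity`, `is_empty`.
#' @export
summarize_cells <- function(m) {
  stopifnot(inherits(m, "bin_cell_matrix"))
  lib <- Matrix::colSums(m$counts)
  nnz <- diff(m$counts@p)
  data.frame(barcode = m$barcodes,
             library_size = lib,
             sparsity = 1 - nnz / nrow(m$counts),
             is_empty = lib == 0,
             stringsAsFactors = FALSE)
}
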