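# internal coercion: anything matrix-like -> clean dgCMatrix without
# explicit zeros
as_dgc <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::drop0(m)
}

# round half away from zero (the integerization used for additive noise)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# seed guard: run code under a seed without clobbering the caller's RNG
# when seed is NULL
with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
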