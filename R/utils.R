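NUCLEOTIDES <- c("A", "C", "G", "T")

# all k-mers over A/C/G/T in lexicographic order
all_oligos <- function(k) {
  stopifnot(k >= 1)
  out <- NUCLEOTIDES
  if (k > 1) for (i in 2:k) out <- as.vector(t(outer(out, NUCLEOTIDES, paste0)))
  out
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# overlapping windows of width k as a character vector (length L - k + 1)
seq_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k = ", k)
  substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-record substream seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
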