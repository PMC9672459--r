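ENCODING_SCHEMES <- c("onehot", "ncp", "kmer", "pseeiip", "psednc", "pseknc",
                      "dacc", "pcpsednc", "pcpsetnc", "moran")

POSITIONAL_SCHEMES <- c("onehot", "ncp")

EIIP_TABLE <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)

#' Encoder hyperparameters
#'
#' Shared parameters of the composition/correlation encoders. `lam`
#' (\eqn{\lambda}) is the highest correlation rank of the pseudo-composition
#' encoders; `w` their weight factor in `[0, 1]`; `lag` the maximum lag of the
#' covariance and Moran encoders; `k` the tuple size for k-mer counting and
#' PseKNC. Defaults (`lam = 2`, `w = 0.1`, `lag = 2`, `k = 3`) are
#' conservative small-order choices suitable for 99-bp input; all are
#' overridable.
#'
#' @param lam non-negative integer, highest counted correlation rank.
#' @param w weight factor in `[0, 1]`.
#' @param lag positive integer, maximum lag.
#' @param k positive integer, tuple size.
#' @param index_set optional [phys_index_set()]; when `NULL` each encoder
#'   picks its documented default set.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(lam = 2, w = 0.1, lag = 2, k = 3,
                           index_set = NULL) {
  if (lam < 0) stop("lam must be >= 0")
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (lag < 1) stop("lag must be >= 1")
  if (k < 1) stop("k must be >= 1")
  if (!is.null(index_set)) stopifnot(inherits(index_set, "phys_index_set"))
  structure(list(lam = as.integer(lam), w = w, lag = as.integer(lag),
                 k = as.integer(k), index_set = index_set),
            class = "encoder_params")
}

resolve_index_set <- function(params, default, order) {
  iset <- params$index_set %||% default
  if (iset$order != order)
    stop("this encoder needs a '", order, "' index set, got '", iset$order, "'")
  if (!iset$standardized) iset <- standardize_indices(iset)
  iset
}

# per-window index profile: (L - k + 1) x n_indices, NA rows for windows
# containing N
oligo_profile <- function(seq, iset) {
  k <- if (iset$order == "di") 2L else 3L
  win <- seq_windows(seq, k)
  P <- iset$table[match(win, rownames(iset$table)), , drop = FALSE]
  rownames(P) <- NULL
  P
}

#' Zero-pad a positional feature matrix
#'
#' Appends all-zero rows so positional encodings of shorter sequences fill
#' the fixed 99-row model input; existing rows are unchanged.
#'
#' @param m numeric matrix (positions x channels).
#' @param target_rows number of rows after padding (default 99).
#' @return The padded matrix.
#' @export
pad_positional <- function(m, target_rows = 99) {
  if (nrow(m) > target_rows)
    stop("matrix has ", nrow(m), " rows, exceeds target_rows = ", target_rows)
  if (nrow(m) == target_rows) return(m)
  rbind(m, matrix(0, target_rows - nrow(m), ncol(m),
                  dimnames = list(NULL, colnames(m))))
}

#' One-hot positional encoding
#'
#' One row per base with channel order (A, C, G, T): A = (1,0,0,0),
#' C = (0,1,0,0), G = (0,0,1,0), T = (0,0,0,1); N encodes as an all-zero
#' row. Zero-padded to `pad_to` rows, giving the fixed `(99, 4)` model input.
#'
#' @param seq a DNA string (A/C/G/T/N, at most `pad_to` bases).
#' @param pad_to rows after zero padding (default 99); `NULL` for no padding.
#' @return Numeric matrix `pad_to x 4`.
#' @export
encode_one_hot <- function(seq, pad_to = 99) {
  ch <- seq_chars(seq)
  m <- matrix(0, length(ch), 4, dimnames = list(NULL, NUCLEOTIDES))
  hit <- match(ch, NUCLEOTIDES)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  if (is.null(pad_to)) m else pad_positional(m, pad_to)
}

#' Nucleotide chemical property (NCP) positional encoding
#'
#' One (b, c, p) triple per base: `b` = 1 for amino bases (A, C),
#' `c` = 1 for purines (A, G), `p` = 1 for weak hydrogen bonding (A, T);
#' so A = (1,1,1), C = (1,0,0), G = (0,1,0), T = (0,0,1), and N an all-zero
#' row. Zero-padded to `pad_to` rows.
#'
#' @inheritParams encode_one_hot
#' @return Numeric matrix `pad_to x 3` with columns `b`, `c`, `p`.
#' @export
encode_ncp <- function(seq, pad_to = 99) {
  ch <- seq_chars(seq)
  m <- cbind(b = as.numeric(ch %in% c("A", "C")),
             c = as.numeric(ch %in% c("A", "G")),
             p = as.numeric(ch %in% c("A", "T")))
  if (is.null(pad_to)) m else pad_positional(m, pad_to)
}

#' k-mer composition
#'
#' Frequencies of the `4^k` overlapping k-mers in lexicographic order,
#' normalized by the number of windows so entries sum to 1. Windows
#' containing N are excluded from both the count and the normalizer.
#'
#' @param seq a DNA string with `nchar(seq) >= k`.
#' @param k tuple size (default 3).
#' @return Named numeric vector of length `4^k`.
#' @export
encode_kmer <- function(seq, k = 3) {
  win <- seq_windows(seq, k)
  oligos <- all_oligos(k)
  hit <- match(win, oligos)
  n_valid <- sum(!is.na(hit))
  if (n_valid == 0) stop("no N-free window of width ", k, " in sequence")
  counts <- tabulate(hit[!is.na(hit)], nbins = length(oligos))
  stats::setNames(counts / n_valid, oligos)
}

#' PseEIIP trinucleotide encoding
#'
#' Electron-ion interaction pseudopotential encoding: entry for trinucleotide
#' `t` is `EIIP_t * f_t`, where `f_t` is the normalized overlapping
#' trinucleotide frequency and `EIIP_t` combines the three mononucleotide
#' constants (A 0.1260, C 0.1340, G 0.0806, T 0.1335). `mode = "sum"`
#' (default, the common PseEIIP convention) sums the three constants;
#' `mode = "mean"` averages them.
#'
#' @param seq a DNA string of length at least 3.
#' @param mode `"sum"` or `"mean"` combination of mononucleotide constants.
#' @return Named numeric vector of length 64.
#' @export
encode_pseeiip <- function(seq, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  f <- encode_kmer(seq, 3)
  tris <- names(f)
  eiip <- EIIP_TABLE[substr(tris, 1, 1)] + EIIP_TABLE[substr(tris, 2, 2)] +
    EIIP_TABLE[substr(tris, 3, 3)]
  if (mode == "mean") eiip <- eiip / 3
  stats::setNames(as.numeric(eiip) * f, tris)
}

# correlation factors theta_j, j = 1..lam, over the oligo profile P
# ((L-k+1) x m): theta_j = mean over i of mean_u (P[i,u] - P[i+j,u])^2, with
# the printed denominator (number of pairs); NA rows (N windows) contribute 0
pse_thetas <- function(P, lam) {
  n <- nrow(P)
  if (lam >= n) stop("lam = ", lam, " too large for this sequence (needs ",
                     "at least ", lam + 1, " windows, has ", n, ")")
  if (lam == 0) return(numeric(0))
  vapply(seq_len(lam), function(j) {
    d <- P[seq_len(n - j), , drop = FALSE] - P[seq_len(n - j) + j, , drop = FALSE]
    d[is.na(d)] <- 0
    sum(rowMeans(d^2)) / (n - j)
  }, numeric(1))
}

pse_combine <- function(freqs, thetas, w) {
  denom <- sum(freqs) + w * sum(thetas)
  vals <- c(freqs, w * thetas) / denom
  names(vals) <- c(names(freqs),
                   if (length(thetas)) paste0("lambda", seq_along(thetas)))
  vals
}

#' Pseudo dinucleotide composition (PseDNC)
#'
#' Combines the 16 normalized dinucleotide frequencies with `lam`
#' sequence-order correlation factors \eqn{\theta_j}, each the average squared
#' index-profile difference between dinucleotides `j` steps apart, weighted by
#' `w`. Entries sum to 1. Uses the six standardized helical step indices by
#' default.
#'
#' @param seq a DNA string of length at least `lam + 2`.
#' @param params an [encoder_params()].
#' @return Named numeric vector of length `16 + lam`.
#' @export
encode_psednc <- function(seq, params = encoder_params()) {
  iset <- resolve_index_set(params, dinucleotide_indices("core6"), "di")
  pse_combine(encode_kmer(seq, 2), pse_thetas(oligo_profile(seq, iset),
                                              params$lam), params$w)
}

#' Parallel-correlation pseudo dinucleotide composition (PCPseDNC)
#'
#' Identical in form to [encode_psednc()] but computed over the bundled
#' 38-column dinucleotide index set (see [dinucleotide_indices()]; the 32
#' `synth*` columns are a documented synthetic stand-in).
#'
#' @inheritParams encode_psednc
#' @return Named numeric vector of length `16 + lam`.
#' @export
encode_pcpsednc <- function(seq, params = encoder_params()) {
  iset <- resolve_index_set(params, dinucleotide_indices("phys38"), "di")
  pse_combine(encode_kmer(seq, 2), pse_thetas(oligo_profile(seq, iset),
                                              params$lam), params$w)
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' Normalized k-tuple frequencies (summing to 1) combined with `lam`
#' dinucleotide-based correlation factors as in PseDNC. With `k = 2` and
#' equal `lam`, PseKNC equals PseDNC.
#'
#' @param seq a DNA string of length at least `max(k, lam + 2)`.
#' @param params an [encoder_params()] (`k` and `lam` both used).
#' @return Named numeric vector of length `4^k + lam`.
#' @export
encode_pseknc <- function(seq, params = encoder_params()) {
  iset <- resolve_index_set(params, dinucleotide_indices("core6"), "di")
  pse_combine(encode_kmer(seq, params$k),
              pse_thetas(oligo_profile(seq, iset), params$lam), params$w)
}

#' Parallel-correlation pseudo trinucleotide composition (PCPseTNC)
#'
#' Trinucleotide analogue of PseDNC: 64 normalized trinucleotide frequencies
#' plus `lam` correlation factors computed on trinucleotide index profiles
#' (bundled trinucleotide set by default). Entries sum to 1.
#'
#' @param seq a DNA string of length at least `lam + 3`.
#' @param params an [encoder_params()].
#' @return Named numeric vector of length `64 + lam`.
#' @export
encode_pcpsetnc <- function(seq, params = encoder_params()) {
  iset <- resolve_index_set(params, trinucleotide_indices(), "tri")
  pse_combine(encode_kmer(seq, 3), pse_thetas(oligo_profile(seq, iset),
                                              params$lam), params$w)
}

dacc_parts <- function(seq, params) {
  iset <- resolve_index_set(params, dinucleotide_indices("core6"), "di")
  P <- oligo_profile(seq, iset)
  n <- nrow(P)                        # L - 1 dinucleotides
  if (params$lag >= n)
    stop("lag = ", params$lag, " too large for sequence of length ",
         nchar(seq))
  Pbar <- colMeans(P, na.rm = TRUE)
  dev <- sweep(P, 2, Pbar)
  dev[is.na(dev)] <- 0
  list(dev = dev, n = n, idx = colnames(P))
}

#' Dinucleotide auto-cross covariance (DACC)
#'
#' Concatenation of the auto-covariance (DAC: same index correlated with
#' itself at lags `1..lag`) and cross-covariance (DCC: ordered pairs of
#' distinct indices) of the standardized dinucleotide index profiles. Each
#' entry is the average product of deviations from the profile mean, with
#' denominator `L - lag - 1`. Dimension `N^2 * lag` for `N` indices.
#'
#' @param seq a DNA string of length at least `lag + 2`.
#' @param params an [encoder_params()].
#' @return Named numeric vector of length `N^2 * lag`.
#' @export
encode_dacc <- function(seq, params = encoder_params()) {
  parts <- dacc_parts(seq, params)
  dev <- parts$dev; n <- parts$n; idx <- parts$idx
  out <- numeric(0)
  for (u in idx) for (lag in seq_len(params$lag)) {
    i <- seq_len(n - lag)
    out <- c(out, stats::setNames(
      sum(dev[i, u] * dev[i + lag, u]) / (n - lag),
      paste0("DAC.", u, ".lag", lag)))
  }
  for (u1 in idx) for (u2 in idx) {
    if (u1 == u2) next
    for (lag in seq_len(params$lag)) {
      i <- seq_len(n - lag)
      out <- c(out, stats::setNames(
        sum(dev[i, u1] * dev[i + lag, u2]) / (n - lag),
        paste0("DCC.", u1, ".", u2, ".lag", lag)))
    }
  }
  out
}

#' Moran autocorrelation encoding
#'
#' Normalized spatial autocorrelation of each standardized dinucleotide index
#' profile along the sequence:
#' \deqn{I(u, d) = \frac{\sum_i (x_i - \bar x)(x_{i+d} - \bar x)/(L-1-d)}
#'                     {\sum_i (x_i - \bar x)^2/(L-1)}}
#' for lags `d = 1..lag`; a zero-variance profile yields 0 by convention.
#' Dimension `N * lag`.
#'
#' @param seq a DNA string of length at least `lag + 2`.
#' @param params an [encoder_params()].
#' @return Named numeric vector of length `N * lag`.
#' @export
encode_moran <- function(seq, params = encoder_params()) {
  iset <- resolve_index_set(params, dinucleotide_indices("core6"), "di")
  P <- oligo_profile(seq, iset)
  n <- nrow(P)
  if (params$lag >= n)
    stop("lag = ", params$lag, " too large for sequence of length ",
         nchar(seq))
  out <- numeric(0)
  for (u in colnames(P)) {
    x <- P[, u]
    xbar <- mean(x, na.rm = TRUE)
    d0 <- x - xbar
    d0[is.na(d0)] <- 0
    denom <- sum(d0^2) / n
    for (lag in seq_len(params$lag)) {
      i <- seq_len(n - lag)
      val <- if (denom == 0) 0 else
        (sum(d0[i] * d0[i + lag]) / (n - lag)) / denom
      out <- c(out, stats::setNames(val, paste0("Moran.", u, ".lag", lag)))
    }
  }
  out
}

#' Encode one sequence under a named scheme
#'
#' Dispatcher over the ten encoding schemes. Positional schemes (`onehot`,
#' `ncp`) return a zero-padded 99-row matrix; composition schemes return a
#' feature vector computed on the unpadded sequence (padding would corrupt
#' frequency statistics).
#'
#' @param seq a DNA string.
#' @param scheme one of `onehot`, `ncp`, `kmer`, `pseeiip`, `psednc`,
#'   `pseknc`, `dacc`, `pcpsednc`, `pcpsetnc`, `moran`.
#' @param params an [encoder_params()].
#' @param pad_to row count for positional schemes (default 99).
#' @return A matrix (positional schemes) or named numeric vector.
#' @export
encode_sequence <- function(seq, scheme, params = encoder_params(),
                            pad_to = 99) {
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  switch(scheme,
    onehot = encode_one_hot(seq, pad_to),
    ncp = encode_ncp(seq, pad_to),
    kmer = encode_kmer(seq, params$k),
    pseeiip = encode_pseeiip(seq),
    psednc = encode_psednc(seq, params),
    pseknc = encode_pseknc(seq, params),
    dacc = encode_dacc(seq, params),
    pcpsednc = encode_pcpsednc(seq, params),
    pcpsetnc = encode_pcpsetnc(seq, params),
    moran = encode_moran(seq, params))
}

#' Encode a whole dataset
#'
#' @param ds a [seq_dataset()].
#' @param scheme encoding scheme name (see [encode_sequence()]).
#' @param params an [encoder_params()].
#' @param flatten for positional schemes: return a row-major flattened
#'   `n x (99 * channels)` matrix (position-major order, for vector-input
#'   models) instead of a 3-D array.
#' @return For positional schemes an `n x 99 x channels` array (or flattened
#'   matrix); otherwise an `n x p` feature matrix with one row per sequence.
#' @export
encode_dataset <- function(ds, scheme, params = encoder_params(),
                           flatten = FALSE) {
  stopifnot(inherits(ds, "seq_dataset"))
  scheme <- match.arg(scheme, ENCODING_SCHEMES)
  if (scheme %in% POSITIONAL_SCHEMES) {
    mats <- lapply(ds$seq, encode_sequence, scheme = scheme, params = params)
    ch <- ncol(mats[[1]])
    if (flatten) {
      out <- t(vapply(mats, function(m) as.vector(t(m)),
                      numeric(99 * ch)))
      rownames(out) <- ds$id
      colnames(out) <- paste0("pos", rep(seq_len(99), each = ch), ".",
                              rep(colnames(mats[[1]]), 99))
      out
    } else {
      arr <- array(0, dim = c(nrow(ds), 99, ch),
                   dimnames = list(ds$id, NULL, colnames(mats[[1]])))
      for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
      arr
    }
  } else {
    vecs <- lapply(ds$seq, encode_sequence, scheme = scheme, params = params)
    out <- do.call(rbind, vecs)
    rownames(out) <- ds$id
    out
  }
}
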