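# Independent brute-force oracles: literal loop transcriptions of the
# published formulas, written before and kept independent of the package
# implementations they check. No vectorization on purpose.

NUC4 <- c("A", "C", "G", "T")

oracle_oligos <- function(k) {
  if (k == 1) return(NUC4)
  shorter <- oracle_oligos(k - 1)
  out <- character(0)
  for (s in shorter) for (n in NUC4) out <- c(out, paste0(s, n))
  out
}

rand_seq <- function(len, alphabet = NUC4) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

oracle_kmer <- function(seq, k) {
  L <- nchar(seq)
  oligos <- oracle_oligos(k)
  counts <- stats::setNames(numeric(length(oligos)), oligos)
  for (i in 1:(L - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    counts[w] <- counts[w] + 1
  }
  counts / (L - k + 1)
}

oracle_eiip_vec <- function(seq, eiip = c(A = 0.1260, C = 0.1340,
                                          G = 0.0806, T = 0.1335)) {
  f <- oracle_kmer(seq, 3)
  out <- numeric(64)
  tris <- oracle_oligos(3)
  for (t in seq_along(tris)) {
    tri <- tris[t]
    e <- eiip[[substr(tri, 1, 1)]] + eiip[[substr(tri, 2, 2)]] +
      eiip[[substr(tri, 3, 3)]]
    out[t] <- e * f[[tri]]
  }
  stats::setNames(out, tris)
}

# correlation function Theta: mean squared index difference between two
# oligonucleotides under standardized table `tab` (rows = oligos)
oracle_theta_fun <- function(tab, o1, o2) {
  mu <- ncol(tab)
  s <- 0
  for (u in 1:mu) s <- s + (tab[o1, u] - tab[o2, u])^2
  s / mu
}

# theta_j for dinucleotide profiles: (1/(L-1-j)) sum_i Theta(d_i, d_{i+j})
oracle_theta_di <- function(seq, j, tab) {
  L <- nchar(seq)
  s <- 0
  for (i in 1:(L - 1 - j)) {
    d1 <- substr(seq, i, i + 1)
    d2 <- substr(seq, i + j, i + j + 1)
    s <- s + oracle_theta_fun(tab, d1, d2)
  }
  s / (L - 1 - j)
}

oracle_psednc <- function(seq, lam, w, tab) {
  f <- oracle_kmer(seq, 2)
  thetas <- numeric(0)
  if (lam > 0) for (j in 1:lam) thetas <- c(thetas, oracle_theta_di(seq, j, tab))
  denom <- sum(f) + w * sum(thetas)
  out <- numeric(16 + lam)
  for (kk in 1:16) out[kk] <- f[kk] / denom
  if (lam > 0) for (kk in 1:lam) out[16 + kk] <- w * thetas[kk] / denom
  out
}

oracle_pseknc <- function(seq, k, lam, w, tab) {
  f <- oracle_kmer(seq, k)
  thetas <- numeric(0)
  if (lam > 0) for (j in 1:lam) thetas <- c(thetas, oracle_theta_di(seq, j, tab))
  denom <- sum(f) + w * sum(thetas)
  out <- numeric(4^k + lam)
  for (u in 1:(4^k)) out[u] <- f[u] / denom
  if (lam > 0) for (u in 1:lam) out[4^k + u] <- w * thetas[u] / denom
  out
}

# theta_j for trinucleotide profiles: (1/(L-2-j)) sum_i Theta(t_i, t_{i+j})
oracle_theta_tri <- function(seq, j, tab) {
  L <- nchar(seq)
  s <- 0
  for (i in 1:(L - 2 - j)) {
    t1 <- substr(seq, i, i + 2)
    t2 <- substr(seq, i + j, i + j + 2)
    s <- s + oracle_theta_fun(tab, t1, t2)
  }
  s / (L - 2 - j)
}

oracle_pcpsetnc <- function(seq, lam, w, tab) {
  f <- oracle_kmer(seq, 3)
  thetas <- numeric(0)
  if (lam > 0) for (j in 1:lam) thetas <- c(thetas, oracle_theta_tri(seq, j, tab))
  denom <- sum(f) + w * sum(thetas)
  out <- numeric(64 + lam)
  for (kk in 1:64) out[kk] <- f[kk] / denom
  if (lam > 0) for (kk in 1:lam) out[64 + kk] <- w * thetas[kk] / denom
  out
}

# DAC(u, lag) and DCC(u1, u2, lag) with the printed averages over L-1
# dinucleotides and denominator L-lag-1
oracle_dacc <- function(seq, LAG, tab) {
  L <- nchar(seq)
  idx <- colnames(tab)
  pbar <- numeric(length(idx))
  names(pbar) <- idx
  for (u in idx) {
    s <- 0
    for (j in 1:(L - 1)) s <- s + tab[substr(seq, j, j + 1), u]
    pbar[u] <- s / (L - 1)
  }
  out <- numeric(0)
  for (u in idx) for (lag in 1:LAG) {
    s <- 0
    for (i in 1:(L - lag - 1)) {
      d1 <- substr(seq, i, i + 1)
      d2 <- substr(seq, i + lag, i + lag + 1)
      s <- s + (tab[d1, u] - pbar[u]) * (tab[d2, u] - pbar[u])
    }
    out <- c(out, s / (L - lag - 1))
  }
  for (u1 in idx) for (u2 in idx) {
    if (u1 == u2) next
    for (lag in 1:LAG) {
      s <- 0
      for (i in 1:(L - lag - 1)) {
        d1 <- substr(seq, i, i + 1)
        d2 <- substr(seq, i + lag, i + lag + 1)
        s <- s + (tab[d1, u1] - pbar[u1]) * (tab[d2, u2] - pbar[u2])
      }
      out <- c(out, s / (L - lag - 1))
    }
  }
  out
}

oracle_moran <- function(seq, LAG, tab) {
  L <- nchar(seq)
  out <- numeric(0)
  for (u in colnames(tab)) {
    x <- numeric(L - 1)
    for (i in 1:(L - 1)) x[i] <- tab[substr(seq, i, i + 1), u]
    xbar <- mean(x)
    den <- 0
    for (i in 1:(L - 1)) den <- den + (x[i] - xbar)^2
    den <- den / (L - 1)
    for (lag in 1:LAG) {
      num <- 0
      for (i in 1:(L - 1 - lag)) num <- num + (x[i] - xbar) * (x[i + lag] - xbar)
      num <- num / (L - 1 - lag)
      out <- c(out, if (den == 0) 0 else num / den)
    }
  }
  out
}

# pairwise-comparison AUROC: wins + half-ties over all pos/neg pairs
oracle_auroc <- function(y, scores) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) s <- s + 1
    else if (scores[i] == scores[j]) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# per-item counting oracle for the confusion metrics
oracle_metrics <- function(y, pred) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (y[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (y[i] == 0 && pred[i] == 1) fp <- fp + 1
    if (y[i] == 1 && pred[i] == 0) fn <- fn + 1
  }
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(acc = (tp + tn) / length(y),
       sn = tp / (tp + fn), sp = tn / (tn + fp),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
       precision = tp / (tp + fp), recall = tp / (tp + fn))
}
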