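#' Recipe for synthetic promoter datasets
#'
#' Generates labeled sequence sets with the structure the classifier
#' assumes, for testing every stage without external data. Host-type
#' promoters carry degenerate sigma-70-style elements (a -35 `TTGACA` box
#' and a -10 `TATAAT` box at loosely constrained positions); phage-type
#' promoters instead carry a single long phage-RNA-polymerase-style
#' consensus. Motifs are implanted into i.i.d. background sequence with a
#' per-base mutation rate, and layer-1 negatives are hard negatives built by
#' [build_negative_set()], so negatives share 35-40% conserved blocks with
#' their positives by construction.
#'
#' The default motif windows are placed so that every motif straddles a
#' block boundary of the default 8-block partition of a 99-mer (boundaries
#' after positions 13, 26, 39, ...): block shuffling then reliably disrupts
#' the promoter elements of a negative -- the defining property of a hard
#' negative -- while still conserving 35-40% of its positions. A negative
#' retaining both sigma-70 boxes intact would require four conserved blocks,
#' which the generator's three fixed blocks cannot provide, and the 20-bp
#' phage consensus spans three blocks so it can never survive shuffling
#' whole.
#'
#' @param n_per_class sequences per class for layer-1 sets (default 100).
#' @param length sequence length in bp (default 99, the model input).
#' @param mutation_rate per-base probability that an implanted motif base is
#'   replaced by a random other base (default 0.1; must be in `[0, 0.5]`).
#' @param host_motifs list of `list(consensus=, window=)` motifs for
#'   host-type promoters; `window` is the inclusive 1-based range of allowed
#'   start positions.
#' @param phage_motifs same, for phage-type promoters.
#' @param phage_fraction fraction of layer-1 positives that are phage-type
#'   (default 0.25).
#' @param n_phage,n_host class sizes for layer-2 sets (defaults 111 and 382,
#'   the benchmark training proportions).
#' @param background base probabilities for A, C, G, T (default uniform).
#' @param shuffle a [shuffle_config()] for negative generation.
#' @param seed integer seed.
#' @return An object of class `synthetic_recipe`.
#' @export
synthetic_recipe <- function(
    n_per_class = 100, length = 99, mutation_rate = 0.03,
    host_motifs = list(list(consensus = "TTGACA", window = c(22, 26)),
                       list(consensus = "TATAAT", window = c(35, 39))),
    phage_motifs = list(list(consensus = "TAATACGACTCACTATAGGG",
                             window = c(21, 26))),
    phage_fraction = 0.25, n_phage = 111, n_host = 382,
    background = c(0.25, 0.25, 0.25, 0.25),
    shuffle = shuffle_config(), seed = 1) {
  if (mutation_rate < 0 || mutation_rate > 0.5)
    stop("mutation_rate must be in [0, 0.5]")
  for (m in c(host_motifs, phage_motifs)) {
    if (m$window[1] < 1 || m$window[2] + nchar(m$consensus) - 1 > length)
      stop("motif '", m$consensus, "' does not fit within length ", length,
           " at window [", m$window[1], ", ", m$window[2], "]")
  }
  if (phage_fraction < 0 || phage_fraction > 1)
    stop("phage_fraction must be in [0, 1]")
  stopifnot(length(background) == 4, all(background >= 0))
  structure(list(n_per_class = as.integer(n_per_class),
                 length = as.integer(length),
                 mutation_rate = mutation_rate, host_motifs = host_motifs,
                 phage_motifs = phage_motifs,
                 phage_fraction = phage_fraction,
                 n_phage = as.integer(n_phage), n_host = as.integer(n_host),
                 background = background / sum(background),
                 shuffle = shuffle, seed = as.integer(seed)),
            class = "synthetic_recipe")
}

# one promoter sequence: background + implanted, point-mutated motifs
synth_promoter <- function(r, motifs) {
  s <- sample(NUCLEOTIDES, r$length, replace = TRUE, prob = r$background)
  for (m in motifs) {
    start <- if (m$window[1] == m$window[2]) m$window[1] else
      sample(m$window[1]:m$window[2], 1)
    mot <- seq_chars(m$consensus)
    mut <- stats::runif(length(mot)) < r$mutation_rate
    if (any(mut))
      mot[mut] <- vapply(mot[mut], function(b)
        sample(setdiff(NUCLEOTIDES, b), 1), character(1))
    s[start:(start + length(mot) - 1)] <- mot
  }
  paste(s, collapse = "")
}

#' Generate a layer-1 (promoter vs non-promoter) synthetic set
#'
#' `n_per_class` positives (a `phage_fraction` / `1 - phage_fraction`
#' mixture of phage- and host-type promoters, subtype recorded in the id)
#' plus `n_per_class` hard negatives generated from them. Deterministic
#' given `recipe$seed`; each record draws from its own derived substream.
#'
#' @param recipe a [synthetic_recipe()].
#' @return A labeled [seq_dataset()] with `2 * n_per_class` records.
#' @export
generate_layer1_set <- function(recipe) {
  stopifnot(inherits(recipe, "synthetic_recipe"))
  n <- recipe$n_per_class
  rec <- lapply(seq_len(n), function(i) with_seed(derive_seed(recipe$seed, i), {
    phage <- stats::runif(1) < recipe$phage_fraction
    list(id = sprintf("pos_%s_%04d", if (phage) "phage" else "host", i),
         seq = synth_promoter(recipe, if (phage) recipe$phage_motifs
                              else recipe$host_motifs))
  }))
  pos <- seq_dataset(vapply(rec, `[[`, character(1), "id"),
                     vapply(rec, `[[`, character(1), "seq"), "promoter")
  shuf <- recipe$shuffle
  shuf$seed <- derive_seed(recipe$seed, 999983L)
  neg <- build_negative_set(pos, shuf)
  out <- rbind(pos, neg)
  class(out) <- c("seq_dataset", "data.frame")
  out
}

#' Generate a layer-2 (phage vs host promoter) synthetic set
#'
#' `n_phage` phage-type and `n_host` host-type promoters (supporting the
#' unbalanced benchmark proportions), distinguished by their motif content.
#'
#' @param recipe a [synthetic_recipe()].
#' @return A labeled [seq_dataset()] with `n_phage + n_host` records.
#' @export
generate_layer2_set <- function(recipe) {
  stopifnot(inherits(recipe, "synthetic_recipe"))
  mk <- function(n, type, motifs, offset) vapply(seq_len(n), function(i)
    with_seed(derive_seed(recipe$seed, offset + i),
              synth_promoter(recipe, motifs)), character(1))
  seq_dataset(
    c(sprintf("phage_%04d", seq_len(recipe$n_phage)),
      sprintf("host_%04d", seq_len(recipe$n_host))),
    c(mk(recipe$n_phage, "phage", recipe$phage_motifs, 2000000L),
      mk(recipe$n_host, "host", recipe$host_motifs, 3000000L)),
    c(rep("phage", recipe$n_phage), rep("host", recipe$n_host)))
}
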