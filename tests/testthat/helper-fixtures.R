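# small labeled one-hot fixture: motif-bearing positives vs random negatives
toy_onehot <- function(n_per_class, seed = 1) {
  withr::local_seed(seed)
  pos <- vapply(seq_len(n_per_class), function(i) {
    s <- sample(NUC4, 99, replace = TRUE)
    s[40:45] <- c("T", "T", "G", "A", "C", "A")
    s[60:65] <- c("T", "A", "T", "A", "A", "T")
    paste(s, collapse = "")
  }, character(1))
  neg <- vapply(seq_len(n_per_class), function(i) rand_seq(99), character(1))
  ds <- seq_dataset(paste0("s", seq_len(2 * n_per_class)), c(pos, neg),
                    rep(c("promoter", "non_promoter"), each = n_per_class))
  list(x = encode_dataset(ds, "onehot"),
       y = factor(ds$label, levels = c("non_promoter", "promoter")))
}

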