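test_that("one-hot encoding matches the published codes and pads to (99, 4)", {
  m <- encode_one_hot("A")
  expect_equal(dim(m), c(99, 4))
  expect_equal(unname(m[1, ]), c(1, 0, 0, 0))
  m4 <- encode_one_hot("ACGT", pad_to = NULL)
  expect_equal(unname(m4), diag(4))
  full <- encode_one_hot("ACGT")
  expect_equal(full[1:4, ], m4)
  expect_true(all(full[5:99, ] == 0))
  expect_equal(rowSums(encode_one_hot(rand_seq(50), pad_to = NULL)),
               rep(1, 50))
  expect_equal(sum(encode_one_hot("ACGTN", pad_to = NULL)[5, ]), 0)
})

test_that("NCP encoding maps the four bases to their chemical triples", {
  m <- encode_ncp("ACGT", pad_to = NULL)
  expect_equal(unname(m[1, ]), c(1, 1, 1))  # A: amino, purine, weak
  expect_equal(unname(m[2, ]), c(1, 0, 0))  # C
  expect_equal(unname(m[3, ]), c(0, 1, 0))  # G
  expect_equal(unname(m[4, ]), c(0, 0, 1))  # T
  expect_equal(nrow(unique(m)), 4)          # triples identify bases uniquely
  expect_equal(dim(encode_ncp("ACGT")), c(99, 3))
})

test_that("pad_positional appends zero rows and preserves content", {
  m <- matrix(1:8, 4, 2)
  p <- pad_positional(m, 10)
  expect_equal(dim(p), c(10, 2))
  expect_equal(p[1:4, ], m)
  expect_equal(sum(p), sum(m))
  expect_identical(pad_positional(p, 10), p)
  expect_error(pad_positional(p, 5), "exceeds")
})

test_that("kmer frequencies count overlapping windows and sum to 1", {
  v <- encode_kmer("AACG", 3)
  expect_equal(v[["AAC"]], 0.5)
  expect_equal(v[["ACG"]], 0.5)
  expect_equal(sum(v), 1)
  expect_equal(encode_kmer("AAAA", 3)[["AAA"]], 1)
  expect_error(encode_kmer("AC", 3), "shorter than k")
  withr::local_seed(1)
  for (rep in 1:10) {
    s <- rand_seq(sample(10:60, 1))
    k <- sample(1:3, 1)
    expect_equal(encode_kmer(s, k), oracle_kmer(s, k), tolerance = 1e-12)
  }
})

test_that("PseEIIP entries are EIIP sums times trinucleotide frequencies", {
  v <- encode_pseeiip("AAA")
  expect_equal(v[["AAA"]], 3 * 0.1260)
  expect_equal(sum(v != 0), 1)
  expect_equal(encode_pseeiip("TTT")[["TTT"]], 3 * 0.1335)
  expect_length(v, 64)
  expect_equal(encode_pseeiip("AAA", mode = "mean")[["AAA"]], 0.1260)
  s <- "GATTACAGATTACA"
  expect_equal(unname(encode_pseeiip(s)), unname(oracle_eiip_vec(s)),
               tolerance = 1e-12)
})

test_that("PseDNC reduces to dinucleotide frequencies at lambda 0 or w 0", {
  s <- rand_seq(30)
  v0 <- encode_psednc(s, encoder_params(lam = 0))
  expect_equal(unname(v0), unname(encode_kmer(s, 2)), tolerance = 1e-12)
  vw0 <- encode_psednc(s, encoder_params(lam = 3, w = 0))
  expect_equal(unname(vw0[1:16]), unname(v0), tolerance = 1e-12)
  expect_equal(unname(vw0[17:19]), c(0, 0, 0))
})

test_that("PseKNC with k = 2 collapses to PseDNC", {
  s <- rand_seq(25)
  p <- encoder_params(lam = 2, w = 0.1, k = 2)
  expect_equal(unname(encode_pseknc(s, p)), unname(encode_psednc(s, p)),
               tolerance = 1e-12)
})

test_that("pseudo-composition encoders error when lambda exceeds the sequence", {
  expect_error(encode_psednc("ACGT", encoder_params(lam = 5)), "lam")
  expect_error(encode_pcpsetnc("ACGTA", encoder_params(lam = 4)), "lam")
})

test_that("constant index profiles give zero DAC and zero Moran entries", {
  # alternating AC: every dinucleotide is AC or CA; an index assigning both
  # the same value yields a constant profile, so deviations vanish
  s <- strrep("AC", 10)
  tab <- dinucleotide_indices("core6", FALSE)$table[, 1:2]
  tab[, 1] <- seq_len(16)
  tab["CA", 1] <- tab["AC", 1]
  tab[, 2] <- rev(seq_len(16))              # second index: varying profile
  iset <- standardize_indices(phys_index_set("t", "di", tab))
  pm <- encoder_params(lag = 2, index_set = iset)
  v <- encode_dacc(s, pm)
  expect_equal(unname(v[grep("^DAC\\.twist", names(v))]), c(0, 0))
  mor <- encode_moran(s, pm)
  expect_equal(unname(mor[grep("twist", names(mor))]), c(0, 0))
})

test_that("Moran autocorrelation is 1 at the period of a periodic profile", {
  # period-2 sequence with an even-length dinucleotide profile: the profile
  # alternates between two values in equal counts, so lag 2 aligns exactly
  s <- paste0(strrep("AG", 12), "A")
  v <- encode_moran(s, encoder_params(lag = 2))
  lag2 <- v[grep("lag2", names(v))]
  expect_true(all(abs(lag2 - 1) < 1e-9 | abs(lag2) < 1e-9))
})

test_that("feature dimensions match their closed forms", {
  s <- rand_seq(40)
  p <- encoder_params(lam = 2, lag = 2, k = 3)
  expect_equal(dim(encode_one_hot(s)), c(99, 4))
  expect_equal(dim(encode_ncp(s)), c(99, 3))
  expect_length(encode_kmer(s, 3), 64)
  expect_length(encode_pseeiip(s), 64)
  expect_length(encode_psednc(s, p), 16 + 2)
  expect_length(encode_pcpsednc(s, p), 16 + 2)
  expect_length(encode_pcpsetnc(s, p), 64 + 2)
  expect_length(encode_pseknc(s, p), 4^3 + 2)
  expect_length(encode_dacc(s, p), 6^2 * 2)       # N^2 x LAG, N = 6
  expect_length(encode_moran(s, p), 6 * 2)        # N x LAG
  p2 <- encoder_params(lag = 2, index_set = {
    iset <- dinucleotide_indices("core6")
    iset$table <- iset$table[, 1:2]
    iset
  })
  expect_length(encode_dacc(s, p2), 2 * 2 * 2)    # N = 2: dim 8
})

test_that("Pse-family vectors are non-negative and sum to 1", {
  withr::local_seed(4)
  p <- encoder_params(lam = 2, w = 0.1)
  for (rep in 1:10) {
    s <- rand_seq(30)
    for (enc in list(encode_psednc, encode_pcpsednc, encode_pcpsetnc,
                     function(x, pp) encode_pseknc(x, pp))) {
      v <- enc(s, p)
      expect_true(all(v >= 0))
      expect_equal(sum(v), 1, tolerance = 1e-9)
    }
  }
})

test_that("all ten encoders match the brute-force oracles on random 20-mers", {
  withr::local_seed(2024)
  p <- encoder_params(lam = 2, w = 0.1, lag = 2, k = 3)
  tab6 <- dinucleotide_indices("core6")$table
  tab38 <- dinucleotide_indices("phys38")$table
  tabtri <- trinucleotide_indices()$table
  for (rep in 1:25) {
    s <- rand_seq(20)
    # positional schemes: direct reconstruction
    oh <- encode_one_hot(s, pad_to = NULL)
    for (i in 1:20)
      expect_equal(unname(oh[i, ]),
                   as.numeric(NUC4 == substr(s, i, i)))
    nc <- encode_ncp(s, pad_to = NULL)
    for (i in 1:20) {
      b <- substr(s, i, i)
      expect_equal(unname(nc[i, ]),
                   c(b %in% c("A", "C"), b %in% c("A", "G"),
                     b %in% c("A", "T")) * 1)
    }
    expect_equal(unname(encode_kmer(s, 3)), unname(oracle_kmer(s, 3)),
                 tolerance = 1e-9)
    expect_equal(unname(encode_pseeiip(s)), unname(oracle_eiip_vec(s)),
                 tolerance = 1e-9)
    expect_equal(unname(encode_psednc(s, p)),
                 oracle_psednc(s, 2, 0.1, tab6), tolerance = 1e-9)
    expect_equal(unname(encode_pcpsednc(s, p)),
                 oracle_psednc(s, 2, 0.1, tab38), tolerance = 1e-9)
    expect_equal(unname(encode_pseknc(s, p)),
                 oracle_pseknc(s, 3, 2, 0.1, tab6), tolerance = 1e-9)
    expect_equal(unname(encode_pcpsetnc(s, p)),
                 oracle_pcpsetnc(s, 2, 0.1, tabtri), tolerance = 1e-9)
    expect_equal(unname(encode_dacc(s, p)),
                 unname(oracle_dacc(s, 2, tab6)), tolerance = 1e-9)
    expect_equal(unname(encode_moran(s, p)),
                 oracle_moran(s, 2, tab6), tolerance = 1e-9)
  }
})

test_that("encoders are pure: identical output for identical input", {
  s <- rand_seq(50)
  p <- encoder_params()
  for (scheme in c("onehot", "ncp", "kmer", "pseeiip", "psednc", "pseknc",
                   "dacc", "pcpsednc", "pcpsetnc", "moran"))
    expect_identical(encode_sequence(s, scheme, p),
                     encode_sequence(s, scheme, p))
})

test_that("composition encoders skip N windows; positional encode them as zeros", {
  s <- "AAANCCC"
  v <- encode_kmer(s, 3)              # valid windows: AAA, CCC
  expect_equal(v[["AAA"]], 0.5)
  expect_equal(v[["CCC"]], 0.5)
  expect_error(encode_kmer("NNNN", 3), "no N-free window")
})

test_that("encode_dataset shapes and row-major flattening are consistent", {
  ds <- seq_dataset(c("a", "b"), c(rand_seq(99), rand_seq(80)))
  arr <- encode_dataset(ds, "onehot")
  expect_equal(dim(arr), c(2, 99, 4))
  flat <- encode_dataset(ds, "onehot", flatten = TRUE)
  expect_equal(dim(flat), c(2, 396))
  # row-major: first four entries are channels of position 1
  expect_equal(unname(flat[1, 1:4]), unname(arr[1, 1, ]))
  expect_equal(unname(flat[1, 5:8]), unname(arr[1, 2, ]))
  km <- encode_dataset(ds, "kmer")
  expect_equal(dim(km), c(2, 64))
  expect_equal(rownames(km), c("a", "b"))
})
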