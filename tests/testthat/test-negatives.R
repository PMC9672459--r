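test_that("split_blocks partitions with front-loaded remainder", {
  expect_equal(split_blocks("AAAACCCCGGGGTTTT", 8),
               c("AA", "AA", "CC", "CC", "GG", "GG", "TT", "TT"))
  expect_equal(nchar(split_blocks(strrep("A", 99), 8)),
               c(13, 13, 13, 12, 12, 12, 12, 12))
  expect_equal(split_blocks("ACGTACGT", 1), "ACGTACGT")
  s <- rand_seq(99)
  expect_equal(paste(split_blocks(s, 8), collapse = ""), s)
  expect_error(split_blocks("ACG", 8), "exceeds sequence length")
})

test_that("shuffle_config validates its invariants", {
  expect_error(shuffle_config(8, 8), "n_shuffled < n_blocks")
  expect_error(shuffle_config(8, 0), "0 < n_shuffled")
})

test_that("generate_negative is deterministic and conserves blocks", {
  withr::local_seed(5)
  for (rep in 1:25) {
    s <- rand_seq(99)
    cfg <- shuffle_config(seed = sample.int(1e8, 1))
    n1 <- generate_negative(s, cfg)
    n2 <- generate_negative(s, cfg)
    expect_identical(n1, n2)
    expect_equal(nchar(n1), 99)
    expect_equal(sort(split_blocks(n1, 8)), sort(split_blocks(s, 8)))
  }
})

test_that("at least n_blocks - n_shuffled blocks stay in place", {
  withr::local_seed(8)
  for (rep in 1:50) {
    s <- rand_seq(99)
    cfg <- shuffle_config(seed = sample.int(1e8, 1))
    n <- generate_negative(s, cfg)
    in_place <- sum(split_blocks(s, 8) == split_blocks(n, 8))
    expect_gte(in_place, 3)
  }
})

test_that("16-bp example: all blocks equal size, >= 3 in place, 0.375 conserved", {
  s <- "AAAACCCCGGGGTTTT"
  cfg <- shuffle_config(seed = 11)
  n <- generate_negative(s, cfg)
  expect_equal(sort(split_blocks(n, 8)), sort(split_blocks(s, 8)))
  expect_gte(conserved_fraction(s, n, cfg), 0.375)
})

test_that("conserved_fraction matches its definition", {
  cfg <- shuffle_config(seed = 1)
  s <- rand_seq(99)
  expect_equal(conserved_fraction(s, s, cfg), 1.0)
  expect_error(conserved_fraction("ACGT", "ACGTA", cfg), "length mismatch")
  # 99-bp negatives conserve 36, 37 or 39 positions (three fixed blocks)
  withr::local_seed(13)
  fr <- replicate(200, {
    sq <- rand_seq(99)
    ci <- shuffle_config(seed = sample.int(1e8, 1))
    conserved_fraction(sq, generate_negative(sq, ci), ci)
  })
  expect_true(all(fr >= 36 / 99 - 1e-12))
  expect_true(all(fr <= 39 / 99 + 1e-12))
})

test_that("mean conserved fraction sits in the 35-40% band", {
  withr::local_seed(21)
  fr <- vapply(1:1500, function(i) {
    sq <- rand_seq(99)
    ci <- shuffle_config(seed = sample.int(1e8, 1))
    conserved_fraction(sq, generate_negative(sq, ci), ci)
  }, numeric(1))
  expect_gte(mean(fr), 0.35)
  expect_lte(mean(fr), 0.40)
})

test_that("build_negative_set makes one labeled negative per positive", {
  withr::local_seed(3)
  pos <- seq_dataset(paste0("p", 1:100), replicate(100, rand_seq(99)),
                     "promoter")
  neg <- build_negative_set(pos, shuffle_config(seed = 9))
  expect_equal(nrow(neg), 100)
  expect_equal(neg$id, paste0(pos$id, "_neg"))
  expect_true(all(neg$label == "non_promoter"))
  expect_true(all(nchar(neg$seq) == 99))
  # per-record substreams: identical rebuild, independent of other records
  neg2 <- build_negative_set(pos, shuffle_config(seed = 9))
  expect_identical(neg$seq, neg2$seq)
  sub <- build_negative_set(pos[1:10, ], shuffle_config(seed = 9))
  expect_identical(sub$seq, neg$seq[1:10])
  expect_warning(
    out <- build_negative_set(seq_dataset(character(0), character(0)),
                              shuffle_config(seed = 1)),
    "empty")
  expect_equal(nrow(out), 0)
})

test_that("variable-length positives yield equal-length negatives", {
  withr::local_seed(17)
  lens <- sample(40:99, 30, replace = TRUE)
  pos <- seq_dataset(paste0("p", 1:30), vapply(lens, rand_seq, character(1)),
                     "promoter")
  neg <- build_negative_set(pos, shuffle_config(seed = 2))
  expect_equal(nchar(neg$seq), nchar(pos$seq))
})
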