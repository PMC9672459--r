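test_that("sigmoid matches its closed form and identities", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 0.880797, tolerance = 1e-6)
  for (p in c(-3, -1, 2, 10))
    expect_equal(sigmoid(p) + sigmoid(-p), 1, tolerance = 1e-12)
  expect_true(all(diff(sigmoid(seq(-5, 5, 0.5))) > 0))
})

test_that("invalid configuration is rejected with the offending fields named", {
  expect_error(cnn_config(dropout = 1.2, epochs = 0), "dropout")
  expect_error(cnn_config(dropout = 1.2, epochs = 0), "epochs")
  expect_error(cnn_config(optimizer = "sgd"), "optimizer")
  expect_error(cnn_config(conv_kernel = 4), "conv_kernel")
})

test_that("built graph matches the intended architecture exactly", {
  m <- cnn_build(cnn_config(), c(99, 4))
  arch <- cnn_architecture(m)
  expect_equal(arch$type,
               c("Conv1D", "MaxPooling1D", "Dropout",
                 "Conv1D", "MaxPooling1D", "Dropout",
                 "Flatten", "Dense", "Dropout", "Dense"))
  expect_equal(sum(arch$type == "Conv1D"), 2)
  expect_equal(sum(arch$type == "Dropout"), 3)
  # first conv: 16 filters x (5 x 4 channels) + 16 biases = 336
  expect_equal(arch$params[1], 336)
  # spatial flow: 99 -> pool 48 -> pool 23; flatten 23 x 16 = 368
  expect_equal(arch$output[1:6],
               c("(99, 16)", "(48, 16)", "(48, 16)",
                 "(48, 16)", "(23, 16)", "(23, 16)"))
  expect_equal(arch$output[7], "(368)")
  expect_equal(arch$params[arch$layer == "dense_1"], 368 * 64 + 64)
  expect_equal(arch$params[arch$layer == "dense_2"], 65)
  expect_true(all(grepl("l2=0.0001 bias_l2=0.0001",
                        arch$detail[arch$type %in% c("Conv1D", "Dense")])))
  expect_true(all(grepl("rate=0.5", arch$detail[arch$type == "Dropout"])))
  expect_true(grepl("act=sigmoid", arch$detail[10]))
  expect_error(cnn_build(cnn_config(), c(50, 4)), "99")
})

test_that("untrained and trained models emit probabilities in (0, 1)", {
  m <- cnn_build(cnn_config(seed = 3), c(99, 4))
  x <- array(stats::runif(5 * 99 * 4), c(5, 99, 4))
  p <- predict(m, x)
  expect_length(p, 5)
  expect_true(all(p > 0 & p < 1))
  expect_error(predict(m, array(0, c(2, 99, 3))), "shape")
})

test_that("training runs the configured number of epochs and logs them", {
  toy <- toy_onehot(12, seed = 5)
  cfg <- cnn_config(epochs = 4, seed = 2)
  fit <- cnn_fit(toy$x, toy$y, cfg)
  expect_equal(nrow(fit$training_log), 4)
  expect_equal(fit$training_log$epoch, 1:4)
  expect_true(all(is.finite(fit$training_log$loss)))
  expect_error(cnn_fit(toy$x, factor(rep("promoter", 24),
                                     levels = c("non_promoter", "promoter")),
                       cfg),
               "single class")
})

test_that("training on a separable toy set overfits and loss trends down", {
  toy <- toy_onehot(100, seed = 7)
  fit <- cnn_fit(toy$x, toy$y, cnn_config(seed = 4))   # default 85 epochs
  p <- predict(fit, toy$x)
  expect_gte(mean((p >= 0.5) == (toy$y == "promoter")), 0.99)
  # monotone apart from transient minibatch/dropout upticks: final loss is
  # far below the initial one and few epochs sit visibly above the running
  # minimum (absolute slack: near convergence relative jitter is meaningless)
  expect_lt(fit$training_log$loss[85], fit$training_log$loss[1] / 2)
  run_min <- cummin(fit$training_log$loss)
  expect_lte(mean(fit$training_log$loss > run_min + 0.1), 0.05)
})

test_that("seeded training is reproducible", {
  toy <- toy_onehot(10, seed = 9)
  cfg <- cnn_config(epochs = 3, seed = 6)
  f1 <- cnn_fit(toy$x, toy$y, cfg)
  f2 <- cnn_fit(toy$x, toy$y, cfg)
  expect_equal(f1$training_log$loss, f2$training_log$loss, tolerance = 1e-12)
  expect_identical(f1$weights, f2$weights)
})

test_that("prediction preserves order and batch size", {
  toy <- toy_onehot(10, seed = 10)
  fit <- cnn_fit(toy$x, toy$y, cnn_config(epochs = 2, seed = 1))
  p_all <- predict(fit, toy$x)
  p_rev <- predict(fit, toy$x[rev(seq_len(20)), , , drop = FALSE])
  expect_length(p_all, 20)
  expect_equal(unname(p_rev), unname(rev(p_all)), tolerance = 1e-12)
})

test_that("save/load round trip preserves config and predictions exactly", {
  toy <- toy_onehot(8, seed = 11)
  fit <- cnn_fit(toy$x, toy$y, cnn_config(epochs = 2, seed = 8))
  f <- withr::local_tempfile(fileext = ".rds")
  cnn_save(fit, f)
  back <- cnn_load(f)
  expect_identical(back$config, fit$config)
  expect_identical(predict(back, toy$x), predict(fit, toy$x))
  # wrong schema is refused
  saveRDS(list(schema = "phageprom_cnn/999", model = fit), f)
  expect_error(cnn_load(f), "schema")
  writeLines("not a model", f)
  expect_error(cnn_load(f), "cannot read|not a phageprom")
})
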