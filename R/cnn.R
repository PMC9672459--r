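#' Logistic sigmoid
#'
#' \eqn{S(p) = 1 / (1 + e^{-p})}, the output activation of the classifier
#' head.
#'
#' @param p numeric vector.
#' @return Values in (0, 1).
#' @examples
#' sigmoid(0)    # 0.5
#' sigmoid(2)    # 0.880797
#' @export
sigmoid <- function(p) 1 / (1 + exp(-p))

#' CNN architecture and training configuration
#'
#' Defaults define the promoter classifier: two 1-D convolution blocks
#' (16 filters, kernel 5, ReLU, "same" padding), each followed by max pooling
#' (size 4, stride 2) and dropout 0.5; then flatten, a 64-unit ReLU dense
#' layer, dropout 0.5, and a single sigmoid output unit. Kernel and bias L2
#' regularization are both 1e-4 on every convolution and dense layer; the
#' loss is binary cross-entropy, optimized with Adam (learning rate 0.003; the step size is not part of the printed architecture and was chosen as a package default)
#' at batch size 20 for 85 epochs. Training is deterministic given `seed`.
#'
#' @param conv_filters filters per convolution layer.
#' @param conv_kernel convolution kernel width (odd, for "same" padding).
#' @param n_conv_blocks number of conv + pool + dropout blocks.
#' @param pool_size,pool_stride max-pooling window and stride.
#' @param dropout dropout rate in `[0, 1)` after each pooling layer and after
#'   the dense layer.
#' @param dense_units units of the fully connected hidden layer.
#' @param l2,bias_l2 L2 penalty coefficients for kernels and biases.
#' @param loss only `"binary_cross_entropy"`.
#' @param optimizer only `"adam"`.
#' @param batch_size minibatch size.
#' @param epochs number of training epochs.
#' @param activation hidden activation, only `"relu"`.
#' @param output_activation only `"sigmoid"`.
#' @param learning_rate Adam step size.
#' @param class_weight reweight classes inversely to frequency (off by
#'   default).
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_filters = 16, conv_kernel = 5, n_conv_blocks = 2,
                       pool_size = 4, pool_stride = 2, dropout = 0.5,
                       dense_units = 64, l2 = 1e-4, bias_l2 = 1e-4,
                       loss = "binary_cross_entropy", optimizer = "adam",
                       batch_size = 20, epochs = 85, activation = "relu",
                       output_activation = "sigmoid", learning_rate = 0.003,
                       class_weight = FALSE, seed = 1) {
  cfg <- list(conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(conv_kernel),
              n_conv_blocks = as.integer(n_conv_blocks),
              pool_size = as.integer(pool_size),
              pool_stride = as.integer(pool_stride),
              dropout = dropout, dense_units = as.integer(dense_units),
              l2 = l2, bias_l2 = bias_l2, loss = loss, optimizer = optimizer,
              batch_size = as.integer(batch_size), epochs = as.integer(epochs),
              activation = activation, output_activation = output_activation,
              learning_rate = learning_rate,
              class_weight = isTRUE(class_weight), seed = as.integer(seed))
  bad <- character(0)
  if (cfg$conv_filters < 1) bad <- c(bad, "conv_filters")
  if (cfg$conv_kernel < 1 || cfg$conv_kernel %% 2 == 0)
    bad <- c(bad, "conv_kernel")
  if (cfg$n_conv_blocks < 1) bad <- c(bad, "n_conv_blocks")
  if (cfg$pool_size < 1 || cfg$pool_stride < 1)
    bad <- c(bad, "pool_size/pool_stride")
  if (cfg$dropout < 0 || cfg$dropout >= 1) bad <- c(bad, "dropout")
  if (cfg$dense_units < 1) bad <- c(bad, "dense_units")
  if (cfg$l2 < 0 || cfg$bias_l2 < 0) bad <- c(bad, "l2/bias_l2")
  if (loss != "binary_cross_entropy") bad <- c(bad, "loss")
  if (optimizer != "adam") bad <- c(bad, "optimizer")
  if (cfg$batch_size < 1) bad <- c(bad, "batch_size")
  if (cfg$epochs < 1) bad <- c(bad, "epochs")
  if (activation != "relu") bad <- c(bad, "activation")
  if (output_activation != "sigmoid") bad <- c(bad, "output_activation")
  if (cfg$learning_rate <= 0) bad <- c(bad, "learning_rate")
  if (length(bad))
    stop("invalid cnn_config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "cnn_config")
}

pool_out_len <- function(L, size, stride) (L - size) %/% stride + 1L

# ---- minimal 1-D CNN engine (batch-first arrays: B x L x C) ----------------

im2col <- function(X, kernel) {
  d <- dim(X); B <- d[1]; L <- d[2]; C <- d[3]
  pad <- (kernel - 1L) %/% 2L
  Xp <- array(0, c(B, L + 2L * pad, C))
  Xp[, pad + seq_len(L), ] <- X
  col <- matrix(0, B * L, kernel * C)
  for (k in seq_len(kernel)) {
    sl <- Xp[, k + 0:(L - 1L), , drop = FALSE]
    dim(sl) <- c(B * L, C)
    col[, (k - 1L) * C + seq_len(C)] <- sl
  }
  col
}

im2col_bwd <- function(dcol, B, L, C, kernel) {
  pad <- (kernel - 1L) %/% 2L
  dXp <- array(0, c(B, L + 2L * pad, C))
  for (k in seq_len(kernel)) {
    part <- dcol[, (k - 1L) * C + seq_len(C), drop = FALSE]
    dim(part) <- c(B, L, C)
    dXp[, k + 0:(L - 1L), ] <- dXp[, k + 0:(L - 1L), , drop = FALSE] + part
  }
  dXp[, pad + seq_len(L), , drop = FALSE]
}

maxpool_fwd <- function(A, size, stride) {
  d <- dim(A); P <- pool_out_len(d[2], size, stride)
  starts <- (seq_len(P) - 1L) * stride
  best <- A[, starts + 1L, , drop = FALSE]
  chosen <- array(1L, dim(best))
  for (k in seq_len(size)[-1]) {
    sl <- A[, starts + k, , drop = FALSE]
    upd <- sl > best
    best[upd] <- sl[upd]
    chosen[upd] <- k
  }
  list(out = best, chosen = chosen, L_in = d[2])
}

maxpool_bwd <- function(dout, pool, size, stride) {
  d <- dim(dout)
  dA <- array(0, c(d[1], pool$L_in, d[3]))
  starts <- (seq_len(d[2]) - 1L) * stride
  for (k in seq_len(size)) {
    mask <- dout * (pool$chosen == k)
    dA[, starts + k, ] <- dA[, starts + k, , drop = FALSE] + mask
  }
  dA
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

glorot <- function(n_in, n_out, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_weights <- function(cfg, input_shape) {
  k <- cfg$conv_kernel; f <- cfg$conv_filters
  wts <- list()
  C <- input_shape[2]
  for (blk in seq_len(cfg$n_conv_blocks)) {
    wts[[paste0("conv", blk, "_W")]] <- glorot(k * C, f, k * C, k * f)
    wts[[paste0("conv", blk, "_b")]] <- numeric(f)
    C <- f
  }
  L <- input_shape[1]
  for (blk in seq_len(cfg$n_conv_blocks))
    L <- pool_out_len(L, cfg$pool_size, cfg$pool_stride)
  flat <- L * f
  wts$dense_W <- glorot(flat, cfg$dense_units, flat, cfg$dense_units)
  wts$dense_b <- numeric(cfg$dense_units)
  wts$out_W <- glorot(cfg$dense_units, 1L, cfg$dense_units, 1L)
  wts$out_b <- numeric(1)
  wts
}

drop_mask <- function(n, rate) {
  if (rate <= 0) return(NULL)
  (stats::runif(n) >= rate) / (1 - rate)
}

cnn_forward <- function(wts, cfg, X, training = FALSE) {
  d <- dim(X); B <- d[1]
  cache <- list(X = X)
  A <- X
  for (blk in seq_len(cfg$n_conv_blocks)) {
    L <- dim(A)[2]
    col <- im2col(A, cfg$conv_kernel)
    Z <- add_bias(col %*% wts[[paste0("conv", blk, "_W")]],
                  wts[[paste0("conv", blk, "_b")]])
    R <- pmax(Z, 0)
    arr <- R; dim(arr) <- c(B, L, cfg$conv_filters)
    pool <- maxpool_fwd(arr, cfg$pool_size, cfg$pool_stride)
    A <- pool$out
    mask <- if (training) drop_mask(length(A), cfg$dropout) else NULL
    if (!is.null(mask)) A <- A * mask
    cache[[paste0("blk", blk)]] <-
      list(col = col, Z = Z, L = L, pool = pool, mask = mask,
           in_dim = dim(cache$X))
  }
  dA <- dim(A)
  Fl <- A; dim(Fl) <- c(B, dA[2] * dA[3])
  Z3 <- add_bias(Fl %*% wts$dense_W, wts$dense_b)
  A3 <- pmax(Z3, 0)
  mask3 <- if (training) drop_mask(length(A3), cfg$dropout) else NULL
  D3 <- if (is.null(mask3)) A3 else A3 * mask3
  Z4 <- add_bias(D3 %*% wts$out_W, wts$out_b)
  p <- sigmoid(as.numeric(Z4))
  cache$flat_dim <- dA
  cache$Fl <- Fl; cache$Z3 <- Z3; cache$mask3 <- mask3; cache$D3 <- D3
  list(p = p, cache = cache)
}

cnn_backward <- function(wts, cfg, fwd, y, sample_w) {
  cache <- fwd$cache
  B <- length(y)
  grads <- list()
  dZ4 <- matrix((fwd$p - y) * sample_w / B, ncol = 1)
  grads$out_W <- crossprod(cache$D3, dZ4) + 2 * cfg$l2 * wts$out_W
  grads$out_b <- colSums(dZ4) + 2 * cfg$bias_l2 * wts$out_b
  dD3 <- dZ4 %*% t(wts$out_W)
  if (!is.null(cache$mask3)) dD3 <- dD3 * cache$mask3
  dZ3 <- dD3 * (cache$Z3 > 0)
  grads$dense_W <- crossprod(cache$Fl, dZ3) + 2 * cfg$l2 * wts$dense_W
  grads$dense_b <- colSums(dZ3) + 2 * cfg$bias_l2 * wts$dense_b
  dFl <- dZ3 %*% t(wts$dense_W)
  dA <- dFl; dim(dA) <- c(B, cache$flat_dim[2], cache$flat_dim[3])
  for (blk in rev(seq_len(cfg$n_conv_blocks))) {
    bc <- cache[[paste0("blk", blk)]]
    if (!is.null(bc$mask)) dA <- dA * bc$mask
    dR <- maxpool_bwd(dA, bc$pool, cfg$pool_size, cfg$pool_stride)
    dim(dR) <- c(B * bc$L, cfg$conv_filters)
    dZ <- dR * (bc$Z > 0)
    Wn <- paste0("conv", blk, "_W"); bn <- paste0("conv", blk, "_b")
    grads[[Wn]] <- crossprod(bc$col, dZ) + 2 * cfg$l2 * wts[[Wn]]
    grads[[bn]] <- colSums(dZ) + 2 * cfg$bias_l2 * wts[[bn]]
    if (blk > 1) {
      dcol <- dZ %*% t(wts[[Wn]])
      dA <- im2col_bwd(dcol, B, bc$L, cfg$conv_filters, cfg$conv_kernel)
    }
  }
  grads
}

l2_penalty <- function(wts, cfg) {
  kernels <- grep("_W$", names(wts), value = TRUE)
  biases <- grep("_b$", names(wts), value = TRUE)
  cfg$l2 * sum(vapply(wts[kernels], function(w) sum(w^2), numeric(1))) +
    cfg$bias_l2 * sum(vapply(wts[biases], function(w) sum(w^2), numeric(1)))
}

#' Build an untrained promoter CNN
#'
#' Instantiates the layer graph and (seeded) initial weights for a given
#' input shape; [cnn_architecture()] reports the resulting layer table.
#'
#' @param config a [cnn_config()].
#' @param input_shape integer vector `(rows, channels)`; rows must be 99,
#'   the fixed model input length.
#' @return An untrained object of class `phage_cnn`.
#' @export
cnn_build <- function(config = cnn_config(), input_shape = c(99, 4)) {
  stopifnot(inherits(config, "cnn_config"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 2 || input_shape[1] != 99)
    stop("input_shape must be (99, channels)")
  wts <- with_seed(config$seed, init_weights(config, input_shape))
  structure(list(config = config, input_shape = input_shape, weights = wts,
                 training_log = NULL, trained = FALSE, positive = NULL),
            class = "phage_cnn")
}

#' Architecture audit table
#'
#' One row per layer of the built graph with type, output shape, trainable
#' parameter count and the regularization applied, for introspection and
#' testing against the intended architecture.
#'
#' @param model a `phage_cnn`.
#' @return A data frame.
#' @export
cnn_architecture <- function(model) {
  stopifnot(inherits(model, "phage_cnn"))
  cfg <- model$config
  L <- model$input_shape[1]; C <- model$input_shape[2]
  rows <- list()
  add <- function(layer, type, out, params, detail)
    rows[[length(rows) + 1]] <<- data.frame(
      layer = layer, type = type, output = out, params = params,
      detail = detail, stringsAsFactors = FALSE)
  for (blk in seq_len(cfg$n_conv_blocks)) {
    np <- cfg$conv_filters * (cfg$conv_kernel * C) + cfg$conv_filters
    add(paste0("conv1d_", blk), "Conv1D",
        sprintf("(%d, %d)", L, cfg$conv_filters), np,
        sprintf("filters=%d kernel=%d act=%s l2=%g bias_l2=%g",
                cfg$conv_filters, cfg$conv_kernel, cfg$activation, cfg$l2,
                cfg$bias_l2))
    C <- cfg$conv_filters
    L <- pool_out_len(L, cfg$pool_size, cfg$pool_stride)
    add(paste0("maxpool_", blk), "MaxPooling1D",
        sprintf("(%d, %d)", L, C), 0L,
        sprintf("size=%d stride=%d", cfg$pool_size, cfg$pool_stride))
    add(paste0("dropout_", blk), "Dropout", sprintf("(%d, %d)", L, C), 0L,
        sprintf("rate=%g", cfg$dropout))
  }
  flat <- L * C
  add("flatten", "Flatten", sprintf("(%d)", flat), 0L, "")
  add("dense_1", "Dense", sprintf("(%d)", cfg$dense_units),
      flat * cfg$dense_units + cfg$dense_units,
      sprintf("units=%d act=%s l2=%g bias_l2=%g", cfg$dense_units,
              cfg$activation, cfg$l2, cfg$bias_l2))
  add(paste0("dropout_", cfg$n_conv_blocks + 1), "Dropout",
      sprintf("(%d)", cfg$dense_units), 0L, sprintf("rate=%g", cfg$dropout))
  add("dense_2", "Dense", "(1)", cfg$dense_units + 1L,
      sprintf("units=1 act=%s l2=%g bias_l2=%g", cfg$output_activation,
              cfg$l2, cfg$bias_l2))
  do.call(rbind, rows)
}

as_binary_labels <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("y must have exactly 2 levels")
    list(y01 = as.numeric(y == levels(y)[2]), positive = levels(y)[2])
  } else {
    yv <- as.numeric(y)
    if (!all(yv %in% c(0, 1))) stop("numeric y must be 0/1")
    list(y01 = yv, positive = "1")
  }
}

#' Fit the promoter CNN
#'
#' Trains the network with Adam on binary cross-entropy for exactly
#' `config$epochs` epochs at `config$batch_size`, logging loss and accuracy
#' per epoch. Fully deterministic given `config$seed` (initialization,
#' shuffling and dropout all draw from one seeded stream). There is no early
#' stopping and no validation split; classes are unweighted unless
#' `config$class_weight` is set.
#'
#' @param x numeric array `n x 99 x channels` of positional encodings
#'   (e.g. from [encode_dataset()] with scheme `"onehot"`).
#' @param y binary labels: 0/1 numeric or a two-level factor (second level =
#'   positive class).
#' @param config a [cnn_config()].
#' @param verbose print per-epoch progress every 10 epochs.
#' @return A trained `phage_cnn` with a `training_log` data frame
#'   (epoch, loss, acc).
#' @export
cnn_fit <- function(x, y, config = cnn_config(), verbose = FALSE) {
  stopifnot(inherits(config, "cnn_config"))
  if (length(dim(x)) != 3) stop("x must be an n x rows x channels array")
  lab <- as_binary_labels(y)
  y01 <- lab$y01
  n <- dim(x)[1]
  if (length(y01) != n) stop("nrow(x) != length(y)")
  if (length(unique(y01)) < 2)
    stop("training labels contain a single class; need both")
  model <- cnn_build(config, dim(x)[2:3])
  model$positive <- lab$positive
  wts <- model$weights
  sw <- rep(1, n)
  if (config$class_weight) {
    n1 <- sum(y01); n0 <- n - n1
    sw <- ifelse(y01 == 1, n / (2 * n1), n / (2 * n0))
  }
  mom <- lapply(wts, function(w) w * 0)
  vel <- lapply(wts, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  step <- 0L
  log_rows <- vector("list", config$epochs)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- x[idx, , , drop = FALSE]
        yb <- y01[idx]
        fwd <- cnn_forward(wts, config, Xb, training = TRUE)
        p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
        bce <- -mean(sw[idx] * (yb * log(p) + (1 - yb) * log(1 - p)))
        loss <- bce + l2_penalty(wts, config)
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", epoch,
               " (consider lowering learning_rate)")
        grads <- cnn_backward(wts, config, fwd, yb, sw[idx])
        step <- step + 1L
        lr_t <- config$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(wts)) {
          g <- grads[[nm]]
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
          wts[[nm]] <- wts[[nm]] - lr_t * mom[[nm]] / (sqrt(vel[[nm]]) + eps)
        }
        tot_loss <- tot_loss + loss * length(idx)
        tot_correct <- tot_correct + sum((fwd$p >= 0.5) == (yb == 1))
      }
      log_rows[[epoch]] <- data.frame(epoch = epoch, loss = tot_loss / n,
                                      acc = tot_correct / n)
      if (verbose && (epoch %% 10 == 0 || epoch == 1))
        message(sprintf("epoch %3d  loss %.4f  acc %.4f", epoch,
                        tot_loss / n, tot_correct / n))
    }
  })
  model$weights <- wts
  model$training_log <- do.call(rbind, log_rows)
  model$trained <- TRUE
  model
}

#' Predict promoter probabilities
#'
#' @param object a trained `phage_cnn`.
#' @param x array `n x rows x channels` matching the training input shape.
#' @param type `"prob"` for probabilities of the positive class, `"class"`
#'   for thresholded 0/1 calls (threshold 0.5).
#' @param ... unused.
#' @return Numeric vector of length `n`.
#' @export
predict.phage_cnn <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (length(dim(x)) != 3 || !all(dim(x)[2:3] == object$input_shape))
    stop("input shape ", paste(dim(x)[-1], collapse = "x"),
         " does not match model input ",
         paste(object$input_shape, collapse = "x"))
  p <- cnn_forward(object$weights, object$config, x, training = FALSE)$p
  names(p) <- dimnames(x)[[1]]
  if (type == "class") as.numeric(p >= 0.5) else p
}

#' @export
print.phage_cnn <- function(x, ...) {
  cat("<phage_cnn> input (", paste(x$input_shape, collapse = ", "), "), ",
      sum(cnn_architecture(x)$params), " trainable parameters, ",
      if (x$trained) paste0("trained ", nrow(x$training_log), " epochs")
      else "untrained", "\n", sep = "")
  invisible(x)
}

#' @export
summary.phage_cnn <- function(object, ...) {
  print(object)
  print(cnn_architecture(object), row.names = FALSE)
  if (object$trained) {
    tl <- object$training_log
    cat(sprintf("final epoch: loss %.4f, accuracy %.4f\n",
                tl$loss[nrow(tl)], tl$acc[nrow(tl)]))
  }
  invisible(object)
}

#' @export
plot.phage_cnn <- function(x, ...) {
  if (!x$trained) stop("model is untrained; nothing to plot")
  tl <- x$training_log
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(tl$epoch, tl$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(tl$epoch, tl$acc, type = "l", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

CNN_SCHEMA <- "phageprom_cnn/1"

#' Save / load a trained CNN
#'
#' The on-disk artifact stores a schema version, the full configuration and
#' the weight tensors; loading verifies the schema and reproduces
#' predictions bit-for-bit.
#'
#' @param model a `phage_cnn`.
#' @param path file path (`.rds`).
#' @return `cnn_save` returns `path` invisibly; `cnn_load` the restored
#'   `phage_cnn`.
#' @export
cnn_save <- function(model, path) {
  stopifnot(inherits(model, "phage_cnn"))
  saveRDS(list(schema = CNN_SCHEMA, model = model), path)
  invisible(path)
}

#' @rdname cnn_save
#' @export
cnn_load <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model file ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$schema))
    stop("not a phageprom model artifact: ", path)
  if (!identical(obj$schema, CNN_SCHEMA))
    stop("unsupported model schema version '", obj$schema, "' (expected '",
         CNN_SCHEMA, "')")
  obj$model
}
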