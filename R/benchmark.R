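#' Encoding-by-model benchmark grid
#'
#' Cross-validated comparison of encoding schemes against classifiers, the
#' experiment used to select the final encoder/model pair. Each cell runs
#' stratified k-fold CV of one model on one encoding; the CNN participates
#' as an eleventh model (`"cnn"`) on positional encodings. Incompatible
#' pairs (e.g. the CNN on a composition vector, or multinomial naive Bayes
#' on an encoding with negative values) are recorded as `status = "failed"`
#' rows, not errors.
#'
#' @param ds a labeled two-class [seq_dataset()].
#' @param encodings character vector of encoding scheme names.
#' @param models character vector of baseline algorithm names and/or
#'   `"cnn"`.
#' @param k folds (default 5).
#' @param seed integer seed (fold assignment and stochastic learners).
#' @param params an [encoder_params()].
#' @param config a [cnn_config()] for the CNN cells; its `seed` is
#'   overridden by `seed`.
#' @return Data frame with one row per encoding-model pair: `encoding`,
#'   `model`, `acc`, `sn`, `sp`, `mcc`, `auroc`, `status`, sorted by
#'   descending accuracy (failed rows last).
#' @export
benchmark_grid <- function(ds, encodings, models, k = 5, seed = 1,
                           params = encoder_params(),
                           config = cnn_config()) {
  stopifnot(inherits(ds, "seq_dataset"))
  labs <- unique(ds$label[!is.na(ds$label)])
  if (length(labs) != 2 || any(is.na(ds$label)))
    stop("ds must be fully labeled with exactly two classes")
  y <- factor(ds$label, levels = sort(labs))
  encodings <- match.arg(encodings, ENCODING_SCHEMES, several.ok = TRUE)
  feat_flat <- list(); feat_arr <- list()
  rows <- list()
  for (enc in encodings) for (mod in models) {
    res <- tryCatch({
      if (mod == "cnn") {
        if (!enc %in% POSITIONAL_SCHEMES)
          stop("cnn requires a positional encoding")
        if (is.null(feat_arr[[enc]]))
          feat_arr[[enc]] <- encode_dataset(ds, enc, params)
        cfg <- config; cfg$seed <- as.integer(seed)
        trainer <- function(xtr, ytr) cnn_fit(xtr, ytr, cfg)
        kfold_cv(feat_arr[[enc]], y, trainer, k, seed)
      } else {
        mod <- match.arg(mod, BASELINE_ALGORITHMS)
        if (is.null(feat_flat[[enc]]))
          feat_flat[[enc]] <- if (enc %in% POSITIONAL_SCHEMES)
            encode_dataset(ds, enc, params, flatten = TRUE)
          else encode_dataset(ds, enc, params)
        spec <- baseline_spec(mod, seed = seed)
        trainer <- function(xtr, ytr) baseline_fit(spec, xtr, ytr)
        kfold_cv(feat_flat[[enc]], y, trainer, k, seed)
      }
    }, error = function(e) e)
    rows[[paste(enc, mod)]] <- if (inherits(res, "error"))
      data.frame(encoding = enc, model = mod, acc = NA, sn = NA, sp = NA,
                 mcc = NA, auroc = NA, status = "failed",
                 stringsAsFactors = FALSE)
    else
      data.frame(encoding = enc, model = mod, acc = res$mean[["acc"]],
                 sn = res$mean[["sn"]], sp = res$mean[["sp"]],
                 mcc = res$mean[["mcc"]], auroc = res$mean[["auroc"]],
                 status = "ok", stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  grid[order(grid$status != "ok", -ifelse(is.na(grid$acc), -Inf, grid$acc)), ,
       drop = FALSE]
}
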