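#' Assemble a two-layer cascade from fitted models
#'
#' Layer 1 scores promoter vs non-promoter; layer 2 is consulted only for
#' sequences whose layer-1 probability reaches `threshold` and scores phage
#' vs host. The positive convention of layer 2 is *phage*: `p_phage` is the
#' probability that a promoter is recognized by the phage transcription
#' machinery, `1 - p_phage` that it is a host promoter.
#'
#' @param layer1 fitted promoter/non-promoter model (e.g. a `phage_cnn`).
#' @param layer2 fitted phage/host model.
#' @param threshold gating and calling threshold (default 0.5; applied to
#'   both layers).
#' @param scheme positional encoding scheme used to featurize query
#'   sequences (default `"onehot"`).
#' @return An object of class `phage_cascade`.
#' @export
cascade_model <- function(layer1, layer2, threshold = 0.5,
                          scheme = "onehot") {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  structure(list(layer1 = layer1, layer2 = layer2, threshold = threshold,
                 scheme = match.arg(scheme, POSITIONAL_SCHEMES)),
            class = "phage_cascade")
}

#' Train the two-layer promoter cascade
#'
#' Trains two independent CNNs: layer 1 on a promoter/non-promoter dataset
#' and layer 2 on a phage/host promoter dataset, both on the same positional
#' encoding, and packages them with a shared threshold.
#'
#' @param layer1_ds a [seq_dataset()] labeled `promoter` / `non_promoter`.
#' @param layer2_ds a [seq_dataset()] labeled `phage` / `host`.
#' @param config a [cnn_config()] applied to both layers (layer 2 uses
#'   `seed + 1` so the layers do not share an initialization).
#' @param threshold shared decision threshold.
#' @param scheme positional encoding scheme.
#' @param verbose print training progress.
#' @return A `phage_cascade`.
#' @export
cascade_fit <- function(layer1_ds, layer2_ds, config = cnn_config(),
                        threshold = 0.5, scheme = "onehot", verbose = FALSE) {
  stopifnot(inherits(layer1_ds, "seq_dataset"),
            inherits(layer2_ds, "seq_dataset"))
  if (!all(layer1_ds$label %in% c("promoter", "non_promoter")))
    stop("layer1_ds must be labeled promoter/non_promoter")
  if (!all(layer2_ds$label %in% c("phage", "host")))
    stop("layer2_ds must be labeled phage/host")
  x1 <- encode_dataset(layer1_ds, scheme)
  y1 <- factor(layer1_ds$label, levels = c("non_promoter", "promoter"))
  m1 <- cnn_fit(x1, y1, config, verbose = verbose)
  x2 <- encode_dataset(layer2_ds, scheme)
  y2 <- factor(layer2_ds$label, levels = c("host", "phage"))
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  m2 <- cnn_fit(x2, y2, cfg2, verbose = verbose)
  cascade_model(m1, m2, threshold, scheme)
}

#' Predict three-way promoter calls
#'
#' Applies the cascade to every sequence: layer 1 yields `p_promoter`;
#' only when `p_promoter >= threshold` is layer 2 invoked, yielding
#' `p_phage` and a call of `phage_promoter` or `host_promoter`; otherwise
#' the call is `non_promoter` and `p_phage` is `NA`. Order is preserved.
#'
#' @param object a `phage_cascade`.
#' @param ds a [seq_dataset()] of query sequences (at most 99 bp each).
#' @param ... unused.
#' @return Data frame with columns `id`, `p_promoter`, `p_phage`, `call`.
#' @export
predict.phage_cascade <- function(object, ds, ...) {
  stopifnot(inherits(ds, "seq_dataset"))
  empty <- data.frame(id = character(0), p_promoter = numeric(0),
                      p_phage = numeric(0), call = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(ds) == 0) return(empty)
  validate_sequences(ds)
  x <- encode_dataset(ds, object$scheme)
  p1 <- as.numeric(predict(object$layer1, x))
  p2 <- rep(NA_real_, nrow(ds))
  gate <- p1 >= object$threshold
  if (any(gate))
    p2[gate] <- as.numeric(predict(object$layer2,
                                   x[gate, , , drop = FALSE]))
  call <- ifelse(!gate, "non_promoter",
                 ifelse(p2 >= object$threshold, "phage_promoter",
                        "host_promoter"))
  data.frame(id = ds$id, p_promoter = p1, p_phage = p2, call = call,
             stringsAsFactors = FALSE)
}

#' @export
print.phage_cascade <- function(x, ...) {
  cat("<phage_cascade> encoding '", x$scheme, "', threshold ", x$threshold,
      "\n  layer 1 (promoter vs non-promoter): ", sep = "")
  print(x$layer1)
  cat("  layer 2 (phage vs host, positive = phage): ")
  print(x$layer2)
  invisible(x)
}

CASCADE_SCHEMA <- "phageprom_cascade/1"

#' Save / load a cascade
#'
#' @param model a `phage_cascade`.
#' @param path file path (`.rds`).
#' @return `cascade_save` returns `path` invisibly; `cascade_load` the
#'   restored `phage_cascade`.
#' @export
cascade_save <- function(model, path) {
  stopifnot(inherits(model, "phage_cascade"))
  saveRDS(list(schema = CASCADE_SCHEMA, model = model), path)
  invisible(path)
}

#' @rdname cascade_save
#' @export
cascade_load <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read cascade file ", path, ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$schema, CASCADE_SCHEMA))
    stop("not a phageprom cascade artifact: ", path)
  obj$model
}
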