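BASELINE_ALGORITHMS <- c("adaboost", "multinomial_naive_bayes", "xgboost",
                         "gradient_boosting", "logistic_regression", "knn",
                         "decision_tree", "svm", "mlp", "svm_bagging")

#' Specify a baseline classifier
#'
#' Uniform interface over the ten baseline algorithms used in the
#' encoding-versus-model selection experiment. Hyperparameters default to
#' the backing library's defaults (pinned here for transparency) and can be
#' overridden through `params`:
#' \describe{
#'   \item{adaboost}{`n_estimators` (50) decision stumps, SAMME reweighting
#'     (implemented in-package).}
#'   \item{multinomial_naive_bayes}{`alpha` (1) Laplace smoothing; requires
#'     non-negative features (implemented in-package).}
#'   \item{xgboost}{`nrounds` (100), `max_depth` (6), `eta` (0.3).}
#'   \item{gradient_boosting}{classic GBM-style settings on the xgboost
#'     backend: `nrounds` (100), `max_depth` (3), `eta` (0.1), no L2.}
#'   \item{logistic_regression}{binomial GLM, no options.}
#'   \item{knn}{`k` (5) nearest neighbours.}
#'   \item{decision_tree}{CART via rpart, default control.}
#'   \item{svm}{RBF-kernel SVM (e1071), `cost` (1), probability outputs.}
#'   \item{mlp}{single-hidden-layer perceptron (nnet), `size` (16),
#'     `decay` (1e-4), `maxit` (200).}
#'   \item{svm_bagging}{`n_estimators` (10) bootstrap-resampled SVMs,
#'     probabilities averaged.}
#' }
#'
#' @param algorithm one of the ten names above.
#' @param params named list of overrides.
#' @param seed integer seed for stochastic learners.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(algorithm, params = list(), seed = 1) {
  algorithm <- match.arg(algorithm, BASELINE_ALGORITHMS)
  structure(list(algorithm = algorithm, params = params,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

# ---- in-package learners ---------------------------------------------------

# discrete AdaBoost (SAMME) over depth-1 rpart stumps
fit_adaboost <- function(x, y01, n_estimators) {
  n <- length(y01)
  w <- rep(1 / n, n)
  df <- data.frame(y = factor(y01), x)
  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- as.numeric(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (pred != y01))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit
    alphas[m] <- alpha
    w <- w * exp(alpha * ifelse(pred != y01, 1, -1))
    w <- w / sum(w)
    if (err < 1e-9) { stumps <- stumps[seq_len(m)]; alphas <- alphas[seq_len(m)]; break }
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, x) {
  df <- data.frame(x)
  margin <- 0
  for (m in seq_along(fit$stumps)) {
    pred <- as.numeric(as.character(predict(fit$stumps[[m]], df,
                                            type = "class")))
    margin <- margin + fit$alphas[m] * (2 * pred - 1)
  }
  sigmoid(2 * margin)       # squash weighted vote margin to (0, 1)
}

# multinomial naive Bayes on non-negative count/frequency features
fit_mnb <- function(x, y01, alpha) {
  if (any(x < 0))
    stop("multinomial naive Bayes requires non-negative features; ",
         "choose a non-negative encoding (e.g. kmer, onehot)")
  classes <- c(0, 1)
  p <- ncol(x)
  log_theta <- matrix(0, 2, p)
  log_prior <- numeric(2)
  for (ci in 1:2) {
    rows <- x[y01 == classes[ci], , drop = FALSE]
    cs <- colSums(rows) + alpha
    log_theta[ci, ] <- log(cs / sum(cs))
    log_prior[ci] <- log(nrow(rows) / nrow(x))
  }
  list(log_theta = log_theta, log_prior = log_prior)
}

predict_mnb <- function(fit, x) {
  ll <- x %*% t(fit$log_theta)
  ll <- sweep(ll, 2, fit$log_prior, "+")
  1 / (1 + exp(ll[, 1] - ll[, 2]))
}

xgb_fit <- function(x, y01, nrounds, max_depth, eta, lambda, seed) {
  d <- xgboost::xgb.DMatrix(x, label = y01)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, lambda = lambda, nthread = 1, seed = seed),
    d, nrounds = nrounds, verbose = 0)
}

#' Fit a baseline classifier
#'
#' @param spec a [baseline_spec()].
#' @param x numeric feature matrix (`n x p`); positional encodings must be
#'   flattened first (see [encode_dataset()] with `flatten = TRUE`).
#' @param y binary labels: 0/1 numeric or two-level factor (second level =
#'   positive).
#' @return An object of class `phage_baseline` whose [predict()] method
#'   returns positive-class probabilities, the same contract as the CNN.
#' @export
baseline_fit <- function(spec, x, y) {
  stopifnot(inherits(spec, "baseline_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  lab <- as_binary_labels(y)
  y01 <- lab$y01
  if (length(unique(y01)) < 2) stop("need both classes in y")
  p <- spec$params
  fit <- with_seed(spec$seed, switch(spec$algorithm,
    adaboost = fit_adaboost(x, y01, p$n_estimators %||% 50),
    multinomial_naive_bayes = fit_mnb(x, y01, p$alpha %||% 1),
    xgboost = xgb_fit(x, y01, p$nrounds %||% 100, p$max_depth %||% 6,
                      p$eta %||% 0.3, p$lambda %||% 1, spec$seed),
    gradient_boosting = xgb_fit(x, y01, p$nrounds %||% 100,
                                p$max_depth %||% 3, p$eta %||% 0.1, 0,
                                spec$seed),
    logistic_regression = {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y01,
                                             family = stats::binomial()))
      list(coef = ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    },
    knn = list(x = x, y = factor(y01), k = p$k %||% 5),
    decision_tree = rpart::rpart(y ~ ., data = data.frame(y = factor(y01), x),
                                 method = "class"),
    svm = e1071::svm(x, factor(y01), kernel = p$kernel %||% "radial",
                     cost = p$cost %||% 1, probability = TRUE),
    mlp = nnet::nnet(x, y01, size = p$size %||% 16, decay = p$decay %||% 1e-4,
                     maxit = p$maxit %||% 200, entropy = TRUE, trace = FALSE,
                     MaxNWts = 100000),
    svm_bagging = {
      B <- p$n_estimators %||% 10
      lapply(seq_len(B), function(b) {
        repeat {                      # bootstrap must contain both classes
          idx <- sample.int(nrow(x), replace = TRUE)
          if (length(unique(y01[idx])) == 2) break
        }
        e1071::svm(x[idx, , drop = FALSE], factor(y01[idx]),
                   kernel = p$kernel %||% "radial", cost = p$cost %||% 1,
                   probability = TRUE)
      })
    }))
  structure(list(spec = spec, fit = fit, positive = lab$positive,
                 features = colnames(x)),
            class = "phage_baseline")
}

svm_prob <- function(fit, x) {
  pr <- attr(predict(fit, x, probability = TRUE), "probabilities")
  pr[, "1"]
}

#' @rdname baseline_fit
#' @param object a fitted `phage_baseline`.
#' @param type `"prob"` or `"class"`.
#' @param ... unused.
#' @export
predict.phage_baseline <- function(object, x, type = c("prob", "class"),
                                   ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  colnames(x) <- object$features
  fit <- object$fit
  p <- switch(object$spec$algorithm,
    adaboost = predict_adaboost(fit, x),
    multinomial_naive_bayes = as.numeric(predict_mnb(fit, x)),
    xgboost = ,
    gradient_boosting = predict(fit, xgboost::xgb.DMatrix(x)),
    logistic_regression = as.numeric(sigmoid(cbind(1, x) %*% fit$coef)),
    knn = {
      kn <- class::knn(fit$x, x, fit$y, k = fit$k, prob = TRUE)
      win <- attr(kn, "prob")
      ifelse(kn == "1", win, 1 - win)
    },
    decision_tree = predict(fit, data.frame(x), type = "prob")[, "1"],
    svm = svm_prob(fit, x),
    mlp = as.numeric(predict(fit, x)),
    svm_bagging = rowMeans(vapply(fit, svm_prob, numeric(nrow(x)), x = x)))
  p <- as.numeric(p)
  names(p) <- rownames(x)
  if (type == "class") as.numeric(p >= 0.5) else p
}

#' @export
print.phage_baseline <- function(x, ...) {
  cat("<phage_baseline> ", x$spec$algorithm, " (", length(x$features),
      " features, seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}
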