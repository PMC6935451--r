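#' Stratified two-fold split
#'
#' Splits samples into two near-equal folds, stratified by class so the
#' per-class counts of the folds differ by at most one.  Deterministic for
#' a fixed seed.
#'
#' @param labels Vector of class labels.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments (1 or 2).
#' @export
split_two_fold <- function(labels, seed = 0L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    abort(sprintf("Stratification error: class \"%s\" has fewer than 2 samples.",
                  names(tab)[which.min(tab)]))
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(1:2, length(idx))
    }
  })
  folds
}

#' Describe a classifier
#'
#' @param kind One of `"cnn"` (small convolutional network on segmented
#'   images), `"forest"` (tree random forest), `"mlp"` (multilayer
#'   perceptron) or `"bayes"` (naive Bayes network structure).
#' @param seed Integer seed recorded in outputs and used for all
#'   stochastic training steps.
#' @param ... Hyperparameter overrides.  Feature learners: `ntree`
#'   (forest, 200), `size`/`decay`/`maxit` (mlp: 8 / 0.01 / 300),
#'   `laplace` (bayes, 0).  CNN: `side` (input resize, 277 - the only
#'   published value; 227 or any small side is selectable), `filters`
#'   (16), `kernel` (3), `pool` (pool block size; 0 = global pooling,
#'   the default), `pool_type` (`"max"` or `"avg"`), `hidden` (0 =
#'   pooled features feed the output unit directly), `epochs` (150),
#'   `lr` (0.01, Adam).
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("forest", "mlp", "bayes", "cnn"),
                            seed = 0L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    forest = list(ntree = 200L),
    mlp = list(size = 8L, decay = 0.01, maxit = 300L),
    bayes = list(laplace = 0),
    cnn = list(side = 277L, filters = 16L, kernel = 3L, pool = 0L,
               pool_type = "max", hidden = 0L, epochs = 150L, lr = 0.01))
  hp <- utils::modifyList(defaults, list(...))
  structure(list(kind = kind, seed = as.integer(seed), hyper = hp),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> kind: %s, seed: %d\n", x$kind, x$seed))
  cat("  ", paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

label_levels <- c("abnormal", "normal")

# Split a feature tibble into x matrix / y factor.
xy_from_tibble <- function(data) {
  stopifnot("label" %in% names(data))
  y <- factor(as.character(data$label), levels = label_levels)
  xcols <- setdiff(names(data), c("label", "id"))
  xcols <- xcols[vapply(data[xcols], is.numeric, logical(1))]
  x <- as.matrix(data[, xcols, drop = FALSE])
  list(x = x, y = y, cols = xcols)
}

#' Train a classifier and predict test labels
#'
#' For the feature-based kinds (`forest`, `mlp`, `bayes`), `train` and
#' `test` are tibbles with a `label` column and numeric feature columns
#' (e.g. from [dataset_features()]).  For `kind = "cnn"` they must carry
#' an `image` list-column of H x W x 3 arrays (typically segmented
#' thermograms), which are resized square to the configured side before
#' training.  Predictions come with the positive-class ("normal") score
#' attached as attribute `"scores"`.
#'
#' @param spec A [classifier_spec()].
#' @param train,test Tibbles as described above.
#' @return Factor of predicted labels for `test` (empty test set gives an
#'   empty factor), with attribute `scores`.
#' @export
train_predict <- function(spec, train, test) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (nrow(train) == 0L) abort("Degenerate training: empty training set.")
  ytr <- factor(as.character(train$label), levels = label_levels)
  if (length(unique(ytr)) < 2L)
    abort("Degenerate training: a single class in the training set.")
  if (spec$kind == "cnn") return(train_predict_cnn(spec, train, test))

  tr <- xy_from_tibble(train)
  te <- xy_from_tibble(test)
  if (nrow(te$x) == 0L)
    return(structure(factor(character(), levels = label_levels),
                     scores = numeric()))
  hp <- spec$hyper
  fit <- NULL
  scores <- with_seed(spec$seed, switch(spec$kind,
    forest = {
      fit <- randomForest::randomForest(tr$x, tr$y, ntree = hp$ntree,
                                         importance = TRUE)
      predict(fit, te$x, type = "prob")[, "normal"]
    },
    mlp = {
      mu <- colMeans(tr$x)
      sg <- apply(tr$x, 2, stats::sd); sg[sg < 1e-12] <- 1
      xs <- scale(tr$x, mu, sg)
      fit <- nnet::nnet(xs, as.numeric(tr$y == "normal"),
                         size = hp$size, decay = hp$decay, maxit = hp$maxit,
                         entropy = TRUE, trace = FALSE, MaxNWts = 100000L)
      as.numeric(predict(fit, scale(te$x, mu, sg)))
    },
    bayes = {
      fit <- e1071::naiveBayes(tr$x, tr$y, laplace = hp$laplace)
      predict(fit, te$x, type = "raw")[, "normal"]
    }))
  pred <- factor(ifelse(scores >= 0.5, "normal", "abnormal"),
                 levels = label_levels)
  structure(pred, scores = as.numeric(scores), fit = fit)
}

#' Two-fold cross-validated evaluation of a classifier
#'
#' Stratified 2-fold cross-validation: the data are divided into two
#' near-equal parts; the first trains and the second tests, then the
#' roles are switched, so every sample is tested exactly once.  Per-fold
#' and pooled confusion matrices and the full indicator set (including
#' rank AUC from the pooled scores) are returned.
#'
#' @param data Tibble with `label` plus feature columns (or an `image`
#'   list-column for `kind = "cnn"`).
#' @param spec A [classifier_spec()].
#' @param seed Seed for the fold split (the classifier uses its own
#'   recorded seed).
#' @return Object of class `thermo_cv` with fields `folds`, `predictions`
#'   (tibble: id/label/fold/pred/score), `per_fold` (confusion matrices),
#'   `cm` (pooled), `metrics` (one-row tibble), `spec`, `seed`.
#' @export
#' @seealso [tidy.thermo_cv()], [glance.thermo_cv()]
cross_validate <- function(data, spec, seed = 0L) {
  folds <- split_two_fold(data$label, seed)
  pred <- factor(rep(NA_character_, nrow(data)), levels = label_levels)
  score <- numeric(nrow(data))
  for (f in 1:2) {
    tr <- data[folds != f, , drop = FALSE]
    te <- data[folds == f, , drop = FALSE]
    p <- train_predict(spec, tr, te)
    pred[folds == f] <- p
    score[folds == f] <- attr(p, "scores")
  }
  truth <- as.character(data$label)
  per_fold <- lapply(1:2, function(f)
    confusion_matrix(truth[folds == f], pred[folds == f]))
  cm <- confusion_matrix(truth, pred)
  metrics <- classification_metrics(cm, scores = score, truth = truth)
  structure(list(folds = folds,
                 predictions = tibble(
                   id = if ("id" %in% names(data)) data$id else
                     seq_len(nrow(data)),
                   label = truth, fold = folds,
                   pred = as.character(pred), score = score),
                 per_fold = per_fold, cm = cm, metrics = metrics,
                 spec = spec, seed = as.integer(seed)),
            class = "thermo_cv")
}

#' @export
print.thermo_cv <- function(x, ...) {
  cat(sprintf("<thermo_cv> %s, %d samples, 2-fold (seed %d)\n",
              x$spec$kind, length(x$folds), x$seed))
  print(x$cm)
  print(as.data.frame(round(x$metrics, 4)), row.names = FALSE)
  invisible(x)
}

#' Tidy per-fold cross-validation results
#'
#' @param x A `thermo_cv`.
#' @param ... Unused.
#' @return Tibble with one row per fold: fold, counts and indicators.
#' @export
tidy.thermo_cv <- function(x, ...) {
  dplyr::bind_rows(lapply(1:2, function(f) {
    cm <- x$per_fold[[f]]
    dplyr::bind_cols(tibble(fold = f, TP = cm$TP, FP = cm$FP,
                            TN = cm$TN, FN = cm$FN),
                     classification_metrics(cm))
  }))
}

#' One-row summary of a cross-validation run
#'
#' @param x A `thermo_cv`.
#' @param ... Unused.
#' @return One-row tibble: classifier kind, n, pooled indicators.
#' @export
glance.thermo_cv <- function(x, ...) {
  dplyr::bind_cols(tibble(kind = x$spec$kind, n = length(x$folds),
                          seed = x$seed),
                   x$metrics)
}
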