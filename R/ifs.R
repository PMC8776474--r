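#' Specify a classifier family and its hyperparameters
#'
#' Four families are supported, each delegating to the standard R
#' implementation: `decision_tree` (CART with the Gini index, via
#' \pkg{rpart}), `knn` (k-nearest neighbour, via \pkg{class}; default 5
#' neighbours), `random_forest` (via \pkg{randomForest}; default 100
#' trees) and `svm` (RBF kernel, cost 1, via \pkg{e1071}).  All defaults
#' are pinned here so results are reproducible; overrides are echoed into
#' result metadata.
#'
#' @param family One of `"decision_tree"`, `"knn"`, `"random_forest"`,
#'   `"svm"`.
#' @param ... Hyperparameter overrides: `k` (knn), `ntree` (random forest),
#'   `kernel`/`cost` (svm).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("decision_tree", "knn", "random_forest", "svm"),
                            ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    decision_tree = list(split = "gini"),
    knn = list(k = 5L),
    random_forest = list(ntree = 100L),
    svm = list(kernel = "radial", cost = 1))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop(sprintf("argument error: unknown hyperparameter(s) for %s: %s",
                 family, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(list(family = family, hyperparameters = defaults,
                 standardize = family %in% c("knn", "svm")),
            class = "classifier_spec")
}

#' Cross-validation configuration
#'
#' Folds are a seeded stratified partition; confusion counts are pooled
#' over all test folds (every sample contributes to exactly one test
#' fold), matching a single confusion matrix over the whole dataset.
#'
#' @param n_folds Number of folds (default 10).
#' @param stratified Stratify folds by class (default `TRUE`).
#' @param seed Integer seed controlling fold assignment and any classifier
#'   randomness (default 1).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, stratified = TRUE, seed = 1L) {
  structure(list(n_folds = as.integer(n_folds), stratified = isTRUE(stratified),
                 seed = as.integer(seed)), class = "cv_config")
}

# Seeded (stratified) fold assignment: integer fold id per sample.
# Stratification deals each class's shuffled samples onto consecutive fold
# ids, continuing from where the previous class stopped, so folds stay as
# class-balanced as the counts allow and every fold is nonempty; with
# n_folds == n this degenerates to leave-one-out-like folds of size 1.  A
# class of size >= 2 always spans at least two folds, so every training
# fold contains both classes.
make_folds <- function(labels, cv) {
  n <- length(labels)
  if (cv$n_folds < 2L || cv$n_folds > n) {
    stop(sprintf("argument error: n_folds (%d) must be in [2, %d]", cv$n_folds, n),
         call. = FALSE)
  }
  fold <- integer(n)
  set.seed(derive_seed(cv$seed, 0L))
  if (cv$stratified) {
    if (min(table(labels)) < 2L) {
      stop("argument error: stratified folds need at least 2 samples in the smallest class",
           call. = FALSE)
    }
    offset <- 0L
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (offset + seq_along(idx) - 1L) %% cv$n_folds + 1L
      offset <- offset + length(idx)
    }
  } else {
    fold <- rep_len(seq_len(cv$n_folds), n)[sample.int(n)]
  }
  fold
}

# Fit on the training rows and predict the test rows; returns a factor of
# predicted labels with the same levels as `labels`.
fit_predict <- function(train_x, train_y, test_x, spec, seed) {
  hp <- spec$hyperparameters
  lev <- levels(train_y)
  if (spec$standardize) {
    mu <- colMeans(train_x)
    sd_ <- apply(train_x, 2, stats::sd)
    sd_[sd_ == 0 | is.na(sd_)] <- 1
    train_x <- sweep(sweep(train_x, 2, mu), 2, sd_, "/")
    test_x <- sweep(sweep(test_x, 2, mu), 2, sd_, "/")
  }
  pred <- switch(spec$family,
    decision_tree = {
      df <- data.frame(.y = train_y, train_x, check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          parms = list(split = hp$split))
      newdf <- data.frame(test_x, check.names = FALSE)
      stats::predict(fit, newdata = newdf, type = "class")
    },
    knn = {
      set.seed(seed)   # distance ties in neighbour voting
      class::knn(train = train_x, test = test_x, cl = train_y, k = hp$k)
    },
    random_forest = {
      set.seed(seed)
      fit <- randomForest::randomForest(x = train_x, y = train_y,
                                        ntree = hp$ntree)
      stats::predict(fit, newdata = test_x)
    },
    svm = {
      fit <- e1071::svm(x = train_x, y = train_y, kernel = hp$kernel,
                        cost = hp$cost, scale = FALSE)
      stats::predict(fit, newdata = test_x)
    })
  factor(as.character(pred), levels = lev)
}

#' Cross-validate a classifier on a feature subset
#'
#' Runs seeded stratified k-fold cross-validation on the selected columns
#' of a feature matrix: a fresh model is fitted per fold on the training
#' part and applied to the held-out part, and confusion counts are pooled
#' over all folds.  Features are standardized with training-fold
#' mean/standard deviation before knn and svm fits (fitted per fold, so no
#' information leaks from test folds); tree-based families consume raw
#' values.
#'
#' @param fm A `feature_matrix` (or list with `values` and `labels`).
#' @param features Integer vector of feature (column) indices to use;
#'   default all.
#' @param spec A [classifier_spec()].
#' @param cv A [cv_config()].
#' @return Pooled [confusion_counts()] over all test folds.
#' @export
cross_validate <- function(fm, features = NULL, spec = classifier_spec(),
                           cv = cv_config()) {
  labels <- fm$labels
  if (length(unique(labels)) < 2L) {
    stop("validation error: both classes must be present", call. = FALSE)
  }
  x <- fm$values
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  fold <- make_folds(labels, cv)
  predicted <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(cv$n_folds)) {
    test <- fold == f
    predicted[test] <- fit_predict(x[!test, , drop = FALSE], labels[!test],
                                   x[test, , drop = FALSE], spec,
                                   seed = derive_seed(cv$seed, f))
  }
  pool_confusion(labels, predicted)
}

#' Incremental feature selection over a ranked feature list
#'
#' Evaluates classifiers on growing prefixes of an mRMR ranking: for each
#' prefix size `s = 1 .. max_size` the top-`s` features are
#' cross-validated and all six measures recorded.  The optimum model is
#' the prefix with the highest cross-validated MCC; MCC ties break to the
#' smallest prefix.
#'
#' @param fm A `feature_matrix`.
#' @param ranking An `mrmr_ranking` from [mrmr_rank()] (its `feature`
#'   column must index columns of `fm`).
#' @param spec A [classifier_spec()].
#' @param cv A [cv_config()].
#' @param max_size Largest prefix to evaluate (default: the full ranking).
#' @return An object of class `ifs_result`: a `data.frame` with columns
#'   `classifier`, `n_features`, `SN`, `SP`, `ACC`, `MCC`, `precision`,
#'   `F1`, one row per prefix size, with attributes `optimum_size`,
#'   `optimum_metrics`, `spec` and `cv`.
#' @export
run_ifs <- function(fm, ranking, spec = classifier_spec(), cv = cv_config(),
                    max_size = NULL) {
  order_ <- ranking$feature
  p <- ncol(fm$values)
  if (any(order_ < 1L | order_ > p) || anyDuplicated(order_)) {
    stop("validation error: ranking does not index the feature matrix", call. = FALSE)
  }
  if (is.null(max_size)) max_size <- length(order_)
  if (max_size < 1L || max_size > length(order_)) {
    stop("argument error: max_size outside the ranked list", call. = FALSE)
  }
  rows <- vector("list", max_size)
  for (s in seq_len(max_size)) {
    counts <- cross_validate(fm, features = order_[seq_len(s)], spec = spec,
                             cv = cv)
    m <- compute_metrics(counts)
    rows[[s]] <- data.frame(classifier = spec$family, n_features = s,
                            t(unclass(m)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  opt <- which.max(out$MCC)   # which.max returns the first (smallest) maximum
  attr(out, "optimum_size") <- out$n_features[opt]
  attr(out, "optimum_metrics") <- structure(
    unlist(out[opt, c("SN", "SP", "ACC", "MCC", "precision", "F1")]),
    class = "metric_set")
  attr(out, "spec") <- spec
  attr(out, "cv") <- cv
  class(out) <- c("ifs_result", "data.frame")
  out
}

#' @export
print.ifs_result <- function(x, ...) {
  cat(sprintf("ifs_result: %s, %d prefix sizes; optimum %d features (MCC %.3f)\n",
              x$classifier[1], nrow(x), attr(x, "optimum_size"),
              attr(x, "optimum_metrics")[["MCC"]]))
  invisible(x)
}

#' Write an IFS table (plus optimum summary) as TSV
#'
#' @param result An `ifs_result`.
#' @param path Output path for the per-prefix table.
#' @param optimum_path Optional path for a one-row optimum summary.
#' @return `path`, invisibly.
#' @export
write_ifs_table <- function(result, path, optimum_path = NULL) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(optimum_path)) {
    opt <- as.data.frame(result)[result$n_features == attr(result, "optimum_size"), ]
    utils::write.table(opt, optimum_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
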