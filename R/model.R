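# Classifier registry, training, and hyperparameter grid search.
#
# The forest itself is a contract (bagged randomized trees, seedable,
# probability output) satisfied by ranger; the sklearn-style hyperparameter
# names used throughout the interface map onto ranger arguments as:
#   n_estimators -> num.trees, max_depth -> max.depth,
#   max_features "log2" -> mtry = floor(log2(p)),
#   min_samples_split -> min.node.size (minimal node size to split at),
#   max_samples -> sample.fraction (with replacement).

ALGORITHMS <- c("RF", "DT", "SVM", "KNN", "NB")

#' Default random-forest hyperparameters
#'
#' The tuned values shipped as defaults: 250 trees, maximum depth 40,
#' `log2` feature subsampling, minimum node size to split of 3, and
#' bootstrap samples the size of the training set.
#'
#' @return Named list of hyperparameters.
#' @export
default_rf_params <- function() {
  list(n_estimators = 250, max_depth = 40, max_features = "log2",
       min_samples_split = 3, max_samples = 1.0)
}

KNOWN_PARAMS <- list(
  RF  = c("n_estimators", "max_depth", "max_features", "min_samples_split",
          "max_samples"),
  DT  = c("minsplit", "cp", "maxdepth"),
  SVM = c("kernel", "cost", "gamma"),
  KNN = c("k"),
  NB  = c("laplace")
)

#' Specify a classifier
#'
#' @param algorithm One of `"RF"`, `"DT"`, `"SVM"`, `"KNN"`, `"NB"`.
#' @param ... Hyperparameter overrides (names validated per algorithm).
#'   RF defaults to [default_rf_params()]; the other algorithms use their
#'   library defaults (KNN: `k = 5`).
#' @param seed Integer seed used for all stochastic parts of training.
#' @return A `methylarg_spec` object.
#' @export
#' @examples
#' classifier_spec("RF")
#' classifier_spec("KNN", k = 5)
classifier_spec <- function(algorithm, ..., seed = 1L) {
  if (!algorithm %in% ALGORITHMS) {
    stop("unknown algorithm '", algorithm, "'; must be one of ",
         paste(ALGORITHMS, collapse = ", "), call. = FALSE)
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), KNOWN_PARAMS[[algorithm]])
  if (length(unknown) > 0) {
    stop("unknown hyperparameter(s) for ", algorithm, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  params <- switch(algorithm,
    RF = default_rf_params(),
    KNN = list(k = 5),
    list()
  )
  params[names(overrides)] <- overrides
  structure(list(algorithm = algorithm, hyperparameters = params,
                 seed = as.integer(seed)),
            class = "methylarg_spec")
}

#' @export
print.methylarg_spec <- function(x, ...) {
  cat("<classifier spec> ", x$algorithm, "\n", sep = "")
  for (nm in names(x$hyperparameters)) {
    cat("  ", nm, " = ", format(x$hyperparameters[[nm]]), "\n", sep = "")
  }
  cat("  seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

rf_mtry <- function(max_features, p) {
  if (identical(max_features, "log2")) return(max(1L, floor(log2(p))))
  if (identical(max_features, "sqrt")) return(max(1L, floor(sqrt(p))))
  max(1L, as.integer(max_features))
}

#' Train a classifier on an encoded feature table
#'
#' @param features Encoded feature tibble with `label` column
#'   (`"positive"`/`"negative"`) and numeric feature columns.
#' @param spec A [classifier_spec()]. Training is deterministic given
#'   `spec$seed`.
#' @return A `methylarg_model` object whose [predict()] method returns
#'   positive-class probabilities.
#' @export
train_model <- function(features, spec = classifier_spec("RF")) {
  stopifnot(inherits(spec, "methylarg_spec"))
  x <- feature_matrix(features)
  y <- factor(features$label, levels = c("negative", "positive"))
  if (nrow(x) != length(y)) stop("feature/label length mismatch", call. = FALSE)
  if (length(unique(y[!is.na(y)])) < 2 || any(table(y) < 2)) {
    stop("training requires at least 2 samples of each class", call. = FALSE)
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$algorithm,
    RF = {
      df <- data.frame(.label = y, x, check.names = FALSE)
      ranger::ranger(
        dependent.variable.name = ".label", data = df,
        num.trees = hp$n_estimators,
        max.depth = hp$max_depth,
        mtry = rf_mtry(hp$max_features, ncol(x)),
        min.node.size = hp$min_samples_split,
        sample.fraction = hp$max_samples, replace = TRUE,
        probability = TRUE, seed = spec$seed, num.threads = 1
      )
    },
    DT = {
      df <- data.frame(.label = y, x, check.names = FALSE)
      ctrl_args <- hp[intersect(names(hp), c("minsplit", "cp", "maxdepth"))]
      withr::with_seed(spec$seed,
        rpart::rpart(.label ~ ., data = df, method = "class",
                     control = do.call(rpart::rpart.control, ctrl_args)))
    },
    SVM = withr::with_seed(spec$seed, {
      args <- c(list(x = x, y = y, probability = TRUE), hp)
      do.call(e1071::svm, args)
    }),
    KNN = list(train_x = x, train_y = y, k = hp$k),
    NB = {
      laplace <- if (is.null(hp$laplace)) 0 else hp$laplace
      xdf <- as.data.frame(x)
      e1071::naiveBayes(x = xdf, y = y, laplace = laplace)
    }
  )
  structure(list(spec = spec, fit = fit,
                 feature_names = colnames(x),
                 n_train = nrow(x),
                 class_counts = table(features$label)),
            class = "methylarg_model")
}

#' Positive-class probabilities from a trained model
#'
#' @param object A `methylarg_model`.
#' @param newdata Encoded feature tibble or numeric matrix with the model's
#'   feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.methylarg_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (!identical(colnames(x), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(x))) {
      stop("newdata is missing model feature column(s)", call. = FALSE)
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  spec <- object$spec
  switch(spec$algorithm,
    RF = {
      pr <- stats::predict(object$fit, data = as.data.frame(x, check.names = FALSE),
                           num.threads = 1)$predictions
      unname(pr[, "positive"])
    },
    DT = {
      pr <- stats::predict(object$fit,
                           newdata = as.data.frame(x, check.names = FALSE),
                           type = "prob")
      unname(pr[, "positive"])
    },
    SVM = {
      pr <- attr(stats::predict(object$fit, newdata = x, probability = TRUE),
                 "probabilities")
      unname(pr[, "positive"])
    },
    KNN = {
      pred <- withr::with_seed(spec$seed,
        class::knn(train = object$fit$train_x, test = x,
                   cl = object$fit$train_y, k = object$fit$k, prob = TRUE))
      win <- attr(pred, "prob")
      unname(ifelse(pred == "positive", win, 1 - win))
    },
    NB = {
      pr <- stats::predict(object$fit,
                           newdata = as.data.frame(x, check.names = FALSE),
                           type = "raw")
      unname(pr[, "positive"])
    }
  )
}

#' @export
print.methylarg_model <- function(x, ...) {
  cat("<trained ", x$spec$algorithm, " model> ", x$n_train, " samples, ",
      length(x$feature_names), " features\n", sep = "")
  invisible(x)
}

#' Save / load a trained model with a JSON metadata sidecar
#'
#' The archive holds the opaque fitted state; `<path>.json` records the
#' algorithm, hyperparameters, seed, feature names, and package version.
#'
#' @param model A `methylarg_model`.
#' @param path Archive path (e.g. `model.rds`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(
    algorithm = model$spec$algorithm,
    hyperparameters = model$spec$hyperparameters,
    seed = model$spec$seed,
    n_features = length(model$feature_names),
    feature_names = model$feature_names,
    package_version = as.character(utils::packageVersion("methylarg"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "methylarg_model"))
  model
}

#' Default hyperparameter search grids
#'
#' Tree counts `{10, 50, 100, ..., 500}` (11 candidates) and maximum
#' depths `{10, 20, ..., 100}` (10 candidates).
#'
#' @return Named list of candidate vectors.
#' @export
default_grids <- function() {
  list(n_estimators = c(10, 50, 100, 150, 200, 250, 300, 350, 400, 450, 500),
       max_depth = seq(10, 100, by = 10))
}

#' Exhaustive grid search over classifier hyperparameters
#'
#' Every combination in `grid` is scored by mean accuracy over stratified
#' cross-validation folds; ties are broken in favor of the earliest-listed
#' combination (first parameter varying fastest).
#'
#' @param features Encoded feature tibble with labels.
#' @param grid Named list of candidate vectors (default [default_grids()]).
#' @param spec Base [classifier_spec()] whose hyperparameters the grid
#'   overrides.
#' @param folds Number of CV folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @return A list with `best_spec` (a `methylarg_spec`) and `scores`
#'   (a tibble of every combination with its mean CV accuracy).
#' @export
grid_search <- function(features, grid = default_grids(),
                        spec = classifier_spec("RF"), folds = 5, seed = 1L) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    stop("grid must contain at least one non-empty candidate list", call. = FALSE)
  }
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  fold_id <- stratified_folds(features$label, k = folds, seed = seed)
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    sp <- spec
    sp$hyperparameters[names(combos)] <- as.list(combos[i, , drop = FALSE])
    accs <- vapply(seq_len(folds), function(f) {
      fit <- train_model(features[fold_id != f, , drop = FALSE], sp)
      prob <- stats::predict(fit, features[fold_id == f, , drop = FALSE])
      mean((prob >= 0.5) == (features$label[fold_id == f] == "positive"))
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  best <- which.max(scores)  # which.max takes the first maximum: earliest combo
  best_spec <- spec
  best_spec$hyperparameters[names(combos)] <- as.list(combos[best, , drop = FALSE])
  list(best_spec = best_spec,
       scores = dplyr::bind_cols(tibble::as_tibble(combos),
                                 tibble::tibble(mean_accuracy = scores)))
}
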