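# Class-imbalance pre-processing (random over-/under-sampling), the
# classifier training/prediction contract, and impurity-based feature
# importance.

#' Resampling specification
#'
#' @param method \code{"ROS"} (random oversampling of the minority class),
#'   \code{"RUS"} (random undersampling of the majority class) or
#'   \code{"none"}.
#' @param sizePct ROS resampling size: the minority class is grown to
#'   \code{sizePct}\% of the majority count (100 balances the classes, 130
#'   overshoots them; any positive value is accepted).
#' @param seed RNG seed making the resampling deterministic.
#' @return a named list consumed by \code{\link{trainOrthologModel}}.
#' @export
resamplingSpec <- function(method = c("none", "ROS", "RUS"), sizePct = 100,
                           seed = 1L) {
  method <- match.arg(method)
  assertScalarCount(sizePct, "sizePct", min = 1e-9)
  list(method = method, sizePct = sizePct, seed = as.integer(seed))
}

.checkTwoClasses <- function(labels) {
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
}

#' Random oversampling of the minority class
#'
#' Duplicates minority rows by sampling with replacement until the minority
#' count reaches \code{round(sizePct/100 * majority count)}; all original
#' rows are kept and the majority class is untouched. If the target does
#' not exceed the current minority count the data are returned unchanged.
#'
#' @param matrix numeric feature matrix (rows = pairs).
#' @param labels 0/1 vector, one per row.
#' @param sizePct resampling size percentage (see
#'   \code{\link{resamplingSpec}}).
#' @param seed RNG seed.
#' @return list with the resampled \code{matrix} and \code{labels}.
#' @export
#' @examples
#' m <- matrix(rnorm(20), ncol = 2)
#' randomOversample(m, rep(c(0, 1), c(8, 2)), 100, seed = 1)$labels
randomOversample <- function(matrix, labels, sizePct = 100, seed = 1L) {
  labels <- as.integer(labels)
  .checkTwoClasses(labels)
  assertScalarCount(sizePct, "sizePct", min = 1e-9)
  counts <- table(labels)
  minority <- as.integer(names(counts)[which.min(counts)])
  n_min <- min(counts); n_maj <- max(counts)
  target <- round(sizePct / 100 * n_maj)
  if (target <= n_min)
    return(list(matrix = matrix, labels = labels))
  min_rows <- which(labels == minority)
  extra <- withSeed(seed,
                    sample(min_rows, target - n_min, replace = TRUE))
  keep <- c(seq_along(labels), extra)
  list(matrix = matrix[keep, , drop = FALSE], labels = labels[keep])
}

#' Random undersampling of the majority class
#'
#' Samples majority rows without replacement down to the minority count,
#' yielding a balanced set; minority rows are untouched and no row is ever
#' duplicated.
#'
#' @inheritParams randomOversample
#' @return list with the resampled \code{matrix} and \code{labels}.
#' @export
randomUndersample <- function(matrix, labels, seed = 1L) {
  labels <- as.integer(labels)
  .checkTwoClasses(labels)
  counts <- table(labels)
  minority <- as.integer(names(counts)[which.min(counts)])
  n_min <- min(counts)
  maj_rows <- which(labels != minority)
  min_rows <- which(labels == minority)
  kept_maj <- withSeed(seed, sample(maj_rows, n_min, replace = FALSE))
  keep <- sort(c(min_rows, kept_maj))
  list(matrix = matrix[keep, , drop = FALSE], labels = labels[keep])
}

#' Default tree hyperparameters
#'
#' Mirrors the defaults of the big-data tree learners this contract maps
#' onto: 100 trees, maximum depth 5, at least 2 instances per node, no
#' minimum information gain, Gini impurity.
#'
#' @param numTrees forest size (random forest only).
#' @param maxDepth maximum tree depth.
#' @param minInstancesPerNode minimum instances in a child node.
#' @param minInfoGain minimum impurity decrease for a split.
#' @param impurity \code{"gini"} or \code{"entropy"} (decision tree only;
#'   the random forest backend supports Gini and falls back to it with a
#'   warning).
#' @return named list.
#' @export
treeHyperparams <- function(numTrees = 100L, maxDepth = 5L,
                            minInstancesPerNode = 2L, minInfoGain = 0,
                            impurity = c("gini", "entropy")) {
  list(numTrees = as.integer(numTrees), maxDepth = as.integer(maxDepth),
       minInstancesPerNode = as.integer(minInstancesPerNode),
       minInfoGain = minInfoGain, impurity = match.arg(impurity))
}

.SUPPORTED_ALGOS <- c("random_forest", "decision_tree", "svm", "logreg",
                      "naive_bayes")

#' Train an ortholog/non-ortholog classifier
#'
#' Applies the resampling specification, then fits the named algorithm.
#' Random forest and decision tree are the first-class algorithms (and the
#' only ones supporting \code{\link{featureImportance}}); \code{svm},
#' \code{logreg} and \code{naive_bayes} honour the same train/predict
#' contract. Training is deterministic given data, hyperparameters and
#' seed.
#'
#' @param x a \code{\link{PairFeatures}} object with labels, or a numeric
#'   matrix.
#' @param labels 0/1 vector (ignored when \code{x} carries labels).
#' @param algorithm one of \code{random_forest}, \code{decision_tree},
#'   \code{svm}, \code{logreg}, \code{naive_bayes}.
#' @param hyperparams see \code{\link{treeHyperparams}}.
#' @param resampling a \code{\link{resamplingSpec}}.
#' @param seed RNG seed for the fit itself.
#' @return an \code{\link{OrthologModel}}.
#' @export
trainOrthologModel <- function(x, labels = NULL,
                               algorithm = c("random_forest",
                                             "decision_tree", "svm",
                                             "logreg", "naive_bayes"),
                               hyperparams = treeHyperparams(),
                               resampling = resamplingSpec("none"),
                               seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is(x, "PairFeatures")) {
    labels <- pairLabels(x)
    if (is.null(labels)) stop("PairFeatures object carries no labels",
                              call. = FALSE)
    x <- featureMatrix(x)
  }
  labels <- as.integer(labels)
  if (anyNA(x)) stop("missing feature values", call. = FALSE)
  .checkTwoClasses(labels)
  before <- c(neg = sum(labels == 0L), pos = sum(labels == 1L))
  res <- switch(resampling$method,
    ROS = randomOversample(x, labels, resampling$sizePct, resampling$seed),
    RUS = randomUndersample(x, labels, resampling$seed),
    none = list(matrix = x, labels = labels))
  if (min(table(res$labels)) < 2L)
    stop("need at least 2 rows per class after resampling", call. = FALSE)
  after <- c(neg = sum(res$labels == 0L), pos = sum(res$labels == 1L))
  df <- as.data.frame(res$matrix)
  names(df) <- make.names(colnames(res$matrix))  # formula-safe aliases
  df$.label <- factor(res$labels, levels = c(0L, 1L))
  fit <- withSeed(seed, switch(algorithm,
    random_forest = {
      if (hyperparams$impurity == "entropy")
        warning("random forest backend supports gini impurity; ",
                "falling back to gini")
      ranger::ranger(
        dependent.variable.name = ".label", data = df,
        num.trees = hyperparams$numTrees,
        max.depth = hyperparams$maxDepth,
        min.node.size = hyperparams$minInstancesPerNode,
        importance = "impurity", seed = as.integer(seed),
        num.threads = 1L, respect.unordered.factors = TRUE)
    },
    decision_tree = rpart::rpart(
      .label ~ ., data = df, method = "class",
      parms = list(split = if (hyperparams$impurity == "entropy")
        "information" else "gini"),
      control = rpart::rpart.control(
        maxdepth = hyperparams$maxDepth,
        minbucket = hyperparams$minInstancesPerNode,
        minsplit = 2L * hyperparams$minInstancesPerNode,
        cp = hyperparams$minInfoGain, xval = 0L)),
    svm = {
      requireNamespace("e1071")
      e1071::svm(.label ~ ., data = df, kernel = "linear", cost = 1)
    },
    logreg = stats::glm(.label ~ ., data = df,
                        family = stats::binomial()),
    naive_bayes = {
      requireNamespace("e1071")
      e1071::naiveBayes(.label ~ ., data = df)
    }))
  new("OrthologModel", algorithm = algorithm, fit = fit,
      featureNames = colnames(x), resampling = resampling,
      classCounts = list(before = before, after = after),
      hyperparams = hyperparams, seed = as.integer(seed))
}

#' Predict ortholog labels
#'
#' @param model an \code{\link{OrthologModel}}.
#' @param x a \code{\link{PairFeatures}} object or numeric matrix whose
#'   columns match the training features (same names, same order);
#'   mismatches raise an error naming the offending column.
#' @return integer vector of 0/1 labels, one per row (length 0 for an
#'   empty matrix).
#' @export
predictOrthologs <- function(model, x) {
  stopifnot(is(model, "OrthologModel"))
  if (is(x, "PairFeatures")) x <- featureMatrix(x)
  cn <- as.character(colnames(x))
  if (!identical(cn, model@featureNames)) {
    off <- if (length(cn) == length(model@featureNames))
      cn[cn != model@featureNames][1]
    else
      c(setdiff(cn, model@featureNames),
        setdiff(model@featureNames, cn), "<column count>")[1]
    stop("feature columns do not match the training order; first ",
         "offending column: '", off, "'", call. = FALSE)
  }
  if (nrow(x) == 0L) return(integer(0))
  df <- as.data.frame(x)
  names(df) <- make.names(cn)
  out <- switch(model@algorithm,
    random_forest = stats::predict(model@fit, data = df,
                                   num.threads = 1L)$predictions,
    decision_tree = stats::predict(model@fit, newdata = df,
                                   type = "class"),
    svm = stats::predict(model@fit, newdata = df),
    logreg = factor(as.integer(
      stats::predict(model@fit, newdata = df, type = "response") > 0.5),
      levels = c(0L, 1L)),
    naive_bayes = stats::predict(model@fit, newdata = df))
  as.integer(as.character(out))
}

#' @rdname featureImportance
#' @export
setMethod("featureImportance", "OrthologModel", function(model) {
  if (!model@algorithm %in% c("random_forest", "decision_tree"))
    stop("feature importance is defined for tree-based models only (got ",
         model@algorithm, ")", call. = FALSE)
  alias <- make.names(model@featureNames)
  raw <- switch(model@algorithm,
    random_forest = ranger::importance(model@fit),
    decision_tree = model@fit$variable.importance)
  imp <- setNames(numeric(length(alias)), alias)
  if (length(raw)) imp[names(raw)] <- raw
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- model@featureNames
  imp
})
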