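#' @rdname PairFeatures-class
#' @param x a \code{PairFeatures} object.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname PairFeatures-class
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname PairFeatures-class
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname PairFeatures-class
#' @param value integer 0/1 vector, one label per pair.
#' @export
setGeneric("pairLabels<-", function(x, value) standardGeneric("pairLabels<-"))

#' @rdname PairFeatures-class
#' @export
setGeneric("percentIdentities",
           function(x) standardGeneric("percentIdentities"))

#' @rdname GoldLabels-class
#' @param x a \code{GoldLabels} object.
#' @export
setGeneric("orthologPairs", function(x) standardGeneric("orthologPairs"))

#' Impurity-based feature importance of a tree model
#'
#' Mean-decrease-in-impurity importances of a fitted tree-based ortholog
#' classifier, normalized to sum to 1 over the features with nonzero
#' importance.
#'
#' @param model a tree-based \code{\link{OrthologModel}} (random forest or
#'   decision tree); other algorithms raise an error.
#' @return named numeric vector over the training features, non-negative,
#'   summing to 1 (all zero only if the model never split).
#' @export
setGeneric("featureImportance",
           function(model) standardGeneric("featureImportance"))

# -- accessors ---------------------------------------------------------------

#' @rdname PairFeatures-class
#' @export
setMethod("featureMatrix", "PairFeatures", function(x) x@features)

#' @rdname PairFeatures-class
#' @export
setMethod("pairIds", "PairFeatures",
          function(x) x@pairs[, c("id1", "id2")])

#' @rdname PairFeatures-class
#' @export
setMethod("pairLabels", "PairFeatures",
          function(x) if (length(x@label)) x@label else NULL)

#' @rdname PairFeatures-class
#' @export
setReplaceMethod("pairLabels", "PairFeatures", function(x, value) {
  x@label <- as.integer(value)
  validObject(x)
  x
})

#' @rdname PairFeatures-class
#' @export
setMethod("percentIdentities", "PairFeatures", function(x) {
  if ("identity_pct" %in% names(x@pairs)) x@pairs$identity_pct
  else rep(NA_real_, nrow(x@pairs))
})

#' @rdname GoldLabels-class
#' @export
setMethod("orthologPairs", "GoldLabels", function(x) x@pairs)

#' Metric values of an evaluation report as a named list
#'
#' @param report an \code{\link{EvaluationReport}}.
#' @return list with tp, tn, fp, fn, tpr, tnr, g_mean, auc_point,
#'   imbalance_ratio, twilight_n, twilight_tp_pct.
#' @export
metricValues <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  list(tp = report@tp, tn = report@tn, fp = report@fp, fn = report@fn,
       tpr = report@tpr, tnr = report@tnr, g_mean = report@gMean,
       auc_point = report@aucPoint, imbalance_ratio = report@imbalanceRatio,
       twilight_n = report@twilight$n,
       twilight_tp_pct = report@twilight$tpPct)
}

# -- show methods ------------------------------------------------------------

setMethod("show", "GoldLabels", function(object) {
  cat("GoldLabels:", nrow(object@pairs), "curated ortholog pairs over a",
      length(object@ids1), "x", length(object@ids2), "pair universe\n")
  n_pos <- nrow(object@pairs)
  n_all <- length(object@ids1) * length(object@ids2)
  cat("  implied negatives:", n_all - n_pos,
      sprintf("(IR = %.3f)\n", (n_all - n_pos) / max(n_pos, 1L)))
})

setMethod("show", "PairFeatures", function(object) {
  cat("PairFeatures:", nrow(object@features), "pairs x",
      ncol(object@features), "features\n")
  cat("  features:", paste(head(colnames(object@features), 6), collapse = ", "),
      if (ncol(object@features) > 6) "..." else "", "\n")
  if (length(object@label))
    cat("  labels:", sum(object@label == 1L), "positive /",
        sum(object@label == 0L), "negative\n")
})

setMethod("show", "OrthologModel", function(object) {
  cat("OrthologModel:", object@algorithm, "\n")
  cat("  resampling:", object@resampling$method,
      if (identical(object@resampling$method, "ROS"))
        paste0("(", object@resampling$sizePct, "%)") else "", "\n")
  cat("  training class counts:",
      paste(names(object@classCounts$after), object@classCounts$after,
            sep = "=", collapse = ", "),
      "(before:", paste(object@classCounts$before, collapse = "/"), ")\n")
  cat("  features:", length(object@featureNames), "\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", as.integer(object@tp),
              as.integer(object@tn), as.integer(object@fp),
              as.integer(object@fn)))
  cat(sprintf("  TPR=%.4f TNR=%.4f G-Mean=%.4f AUC(point)=%.4f IR=%.3f\n",
              object@tpr, object@tnr, object@gMean, object@aucPoint,
              object@imbalanceRatio))
  if (!is.null(object@twilight$n) && !is.na(object@twilight$n))
    cat(sprintf("  twilight (<%g%% id): %d true pairs, %s%% recovered\n",
                object@twilight$threshold %||% 30, object@twilight$n,
                format(object@twilight$tpPct)))
})

setMethod("show", "SyntheticPairSpec", function(object) {
  cat("SyntheticPairSpec\n")
  cat("  orthologs:", object@nOrthologs, " traps:", object@nTraps,
      " background:", object@nBackground1, "/", object@nBackground2, "\n")
  cat("  lengths:", paste(object@lengthRange, collapse = "-"),
      " mutation rate:", object@mutationRate,
      " trap divergence:", object@trapDivergence,
      " seed:", object@seed, "\n")
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult (%s): score=%.1f identity=%.1f%%\n",
              object@mode, object@score, object@identityPct))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
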