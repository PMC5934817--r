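# Imbalance-aware evaluation metrics, twilight-zone analysis and the
# reciprocal-best-hits baseline.

#' Imbalance ratio
#'
#' Negatives over positives; with ~10^4 more non-ortholog pairs than
#' curated orthologs this is the quantity that makes accuracy useless and
#' G-Mean/balanced accuracy the metrics of choice.
#'
#' @param nNeg,nPos class counts; \code{nPos} must be positive.
#' @return \code{nNeg / nPos} (summaries round it to 3 decimals).
#' @export
#' @examples
#' round(imbalanceRatio(31218485, 3062), 3)
imbalanceRatio <- function(nNeg, nPos) {
  if (nPos <= 0) stop("positive count must be > 0", call. = FALSE)
  nNeg / nPos
}

#' Evaluate predicted ortholog labels against the truth
#'
#' Curated orthologs count as positives, all other pairs as negatives.
#' Reports the confusion counts, TPR, TNR, their geometric mean (G-Mean),
#' the single-operating-point balanced accuracy \code{(TPR + TNR)/2}
#' (a one-point AUC: hard labels admit no threshold sweep), the imbalance
#' ratio of the truth, and optionally twilight-zone recovery.
#'
#' @param pred,truth 0/1 vectors of equal length; \code{truth} must
#'   contain both classes.
#' @param identities optional per-pair percent identities enabling the
#'   twilight-zone summary.
#' @param twilightThreshold identity threshold (default 30).
#' @return an \code{\link{EvaluationReport}}.
#' @export
#' @examples
#' r <- evaluateOrthologs(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' metricValues(r)$g_mean
evaluateOrthologs <- function(pred, truth, identities = NULL,
                              twilightThreshold = 30) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth))
    stop("prediction and truth lengths differ", call. = FALSE)
  .checkTwoClasses(truth)
  tp <- sum(pred == 1L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  twilight <- list(n = NA_integer_, tpPct = NA_real_,
                   threshold = twilightThreshold)
  if (!is.null(identities)) {
    tw <- twilightTpPct(pred, truth, identities, twilightThreshold)
    twilight <- list(n = tw[["n"]], tpPct = tw[["tp_pct"]],
                     threshold = twilightThreshold)
  }
  new("EvaluationReport", tp = tp, tn = tn, fp = fp, fn = fn,
      tpr = tpr, tnr = tnr, gMean = sqrt(tpr * tnr),
      aucPoint = (tpr + tnr) / 2,
      imbalanceRatio = imbalanceRatio(sum(truth == 0L), sum(truth == 1L)),
      twilight = twilight)
}

#' Twilight-zone true-positive percentage
#'
#' Restricts to the true ortholog pairs whose percent identity lies below
#' the threshold (remote orthologs, where alignment-based homology
#' inference degrades) and reports how many there are and what percentage
#' of them the classifier recovered.
#'
#' @param pred,truth 0/1 vectors.
#' @param identities per-pair percent identity; must be available (non-NA)
#'   for every true positive pair.
#' @param threshold percent identity delimiting the twilight zone
#'   (default 30).
#' @return named numeric vector \code{c(n = ..., tp_pct = ...)};
#'   \code{tp_pct} is \code{NA} when no true pair falls in the zone.
#' @export
twilightTpPct <- function(pred, truth, identities, threshold = 30) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (anyNA(identities[truth == 1L]))
    stop("identity must be available for every true ortholog pair",
         call. = FALSE)
  zone <- which(truth == 1L & identities < threshold)
  n <- length(zone)
  c(n = n,
    tp_pct = if (n == 0L) NA_real_ else 100 * sum(pred[zone] == 1L) / n)
}

#' Reciprocal-best-hits ortholog prediction
#'
#' The classical unsupervised baseline: Smith-Waterman scores are computed
#' for all pairs and \code{(x, y)} is predicted orthologous iff \code{y} is
#' the unique maximal-scoring partner of \code{x}, \code{x} the unique
#' maximal-scoring partner of \code{y}, and the score reaches
#' \code{minScore}. A tied best score leaves the protein without a best
#' hit (conservative tie rule).
#'
#' @param p1,p2 proteomes (named \code{AAStringSet}s).
#' @param scheme a \code{\link{scoringScheme}}.
#' @param minScore minimal local score to accept a reciprocal pair
#'   (default 0 = no filter; a raw-score stand-in for an E-value cutoff).
#' @param scores optional precomputed \code{length(p1) x length(p2)} local
#'   score matrix (e.g. recycled from a feature run); computed when NULL.
#' @return data.frame of predicted ortholog pairs (columns \code{id1},
#'   \code{id2}).
#' @export
rbhBaseline <- function(p1, p2, scheme = scoringScheme(), minScore = 0,
                        scores = NULL) {
  if (length(p1) == 0L || length(p2) == 0L)
    stop("both proteomes must be non-empty", call. = FALSE)
  if (is.null(scores)) {
    s1 <- as.character(p1); s2 <- as.character(p2)
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(rep(s1, times = length(s2))),
      Biostrings::AAStringSet(rep(s2, each = length(s1))),
      type = "local", substitutionMatrix = .substMatrix(scheme),
      gapOpening = scheme$gapOpen, gapExtension = scheme$gapExtend,
      scoreOnly = TRUE)
    scores <- matrix(pmax(sc, 0), length(p1), length(p2))
  }
  stopifnot(nrow(scores) == length(p1), ncol(scores) == length(p2))
  bestFor <- function(v) {  # unique argmax or NA on ties
    m <- max(v)
    w <- which(v == m)
    if (length(w) == 1L) w else NA_integer_
  }
  best1 <- apply(scores, 1L, bestFor)   # best partner in p2 of each p1
  best2 <- apply(scores, 2L, bestFor)   # best partner in p1 of each p2
  hits <- which(!is.na(best1) &
                best2[ifelse(is.na(best1), 1L, best1)] == seq_along(best1) &
                scores[cbind(seq_along(best1),
                             ifelse(is.na(best1), 1L, best1))] >= minScore)
  data.frame(id1 = names(p1)[hits], id2 = names(p2)[best1[hits]],
             stringsAsFactors = FALSE)
}
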