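#' Curated ortholog labels for a proteome pair
#'
#' Holds the curated positive (ortholog) pairs between two proteomes. The
#' label universe is implicit: every pair of the cross product not listed is
#' a negative (non-ortholog), which is what drives the extreme class
#' imbalance of pairwise ortholog detection.
#'
#' @slot pairs data.frame with character columns \code{id1}, \code{id2}: the
#'   curated ortholog pairs.
#' @slot ids1,ids2 protein identifiers of the first/second proteome, fixing
#'   the implicit all-pairs universe.
#' @seealso \code{\link{loadGoldLabels}}, \code{\link{labelPairs}}
#' @exportClass GoldLabels
setClass("GoldLabels",
  representation(pairs = "data.frame", ids1 = "character", ids2 = "character"))

setValidity("GoldLabels", function(object) {
  p <- object@pairs
  if (!all(c("id1", "id2") %in% names(p)))
    return("'pairs' needs columns 'id1' and 'id2'")
  bad1 <- setdiff(p$id1, object@ids1)
  if (length(bad1)) return(paste0("unknown id in proteome 1: ", bad1[1]))
  bad2 <- setdiff(p$id2, object@ids2)
  if (length(bad2)) return(paste0("unknown id in proteome 2: ", bad2[1]))
  key <- paste(p$id1, p$id2, sep = "\r")
  if (anyDuplicated(key))
    return(paste0("duplicated ortholog pair: ",
                  sub("\r", " / ", key[duplicated(key)][1])))
  if (anyDuplicated(object@ids1) || anyDuplicated(object@ids2))
    return("proteome ids must be unique")
  TRUE
})

#' Pairwise feature matrix for candidate ortholog pairs
#'
#' Rows are candidate protein pairs, columns the named similarity features
#' (29 in the combined configuration). Every column is max-normalized:
#' after \code{\link{normalizeByMax}} its maximum absolute value is 1 unless
#' the column is all zero. Undefined per-pair features are 0, never NA.
#'
#' @slot pairs data.frame with \code{id1}, \code{id2} and, when alignments
#'   were computed, \code{identity_pct} (global-alignment percent identity,
#'   used for twilight-zone analysis).
#' @slot features numeric matrix, one named column per similarity feature.
#' @slot label integer vector of 0/1 labels (length 0 when unknown).
#' @slot params list of the descriptor/alignment parameters used
#'   (provenance; makes the matrix reproducible).
#' @seealso \code{\link{buildFeatureMatrix}}, \code{\link{featureColumnNames}}
#' @exportClass PairFeatures
setClass("PairFeatures",
  representation(pairs = "data.frame", features = "matrix",
                 label = "integer", params = "list"))

setValidity("PairFeatures", function(object) {
  if (nrow(object@features) != nrow(object@pairs))
    return("feature matrix and pair table disagree on row count")
  if (is.null(colnames(object@features)))
    return("feature columns must be named")
  if (length(object@label) && length(object@label) != nrow(object@features))
    return("label length must match the number of pairs")
  if (length(object@label) && !all(object@label %in% c(0L, 1L)))
    return("labels must be 0 (non-ortholog) or 1 (ortholog)")
  if (anyNA(object@features) || any(!is.finite(object@features)))
    return("feature values must be finite (undefined features are 0)")
  TRUE
})

#' A fitted ortholog/non-ortholog classifier
#'
#' Wraps a fitted binary classifier together with the resampling
#' configuration applied before training, the class counts before/after
#' resampling, and the training feature order (prediction enforces it).
#'
#' @slot algorithm one of \code{random_forest}, \code{decision_tree},
#'   \code{svm}, \code{logreg}, \code{naive_bayes}.
#' @slot fit the underlying fitted model object (opaque).
#' @slot featureNames feature columns, in training order.
#' @slot resampling list: \code{method} (ROS/RUS/none), \code{sizePct},
#'   \code{seed}.
#' @slot classCounts list with \code{before} and \code{after} named counts.
#' @slot hyperparams hyperparameters actually used.
#' @slot seed integer seed that fixed the fit.
#' @seealso \code{\link{trainOrthologModel}}, \code{\link{predictOrthologs}},
#'   \code{\link{featureImportance}}
#' @exportClass OrthologModel
setClass("OrthologModel",
  representation(algorithm = "character", fit = "ANY",
                 featureNames = "character", resampling = "list",
                 classCounts = "list", hyperparams = "list",
                 seed = "integer"))

#' Imbalance-aware evaluation of an ortholog classifier
#'
#' Confusion counts and the metrics suited to extreme class imbalance:
#' TPR, TNR, their geometric mean (G-Mean), single-operating-point balanced
#' accuracy, the imbalance ratio of the truth labels, and optionally the
#' recovery of true ortholog pairs in the twilight zone (percent identity
#' below a threshold, default 30).
#'
#' @slot tp,tn,fp,fn confusion counts.
#' @slot tpr,tnr sensitivity and specificity.
#' @slot gMean \code{sqrt(tpr * tnr)}.
#' @slot aucPoint balanced accuracy \code{(tpr + tnr)/2} at the single
#'   operating point of hard labels.
#' @slot imbalanceRatio negatives/positives in the truth labels.
#' @slot twilight list \code{n} (true ortholog pairs under the identity
#'   threshold) and \code{tpPct} (percent of them predicted positive; NA
#'   when \code{n} is 0 or identities were not supplied).
#' @seealso \code{\link{evaluateOrthologs}}, \code{\link{twilightTpPct}}
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(tp = "numeric", tn = "numeric", fp = "numeric",
                 fn = "numeric", tpr = "numeric", tnr = "numeric",
                 gMean = "numeric", aucPoint = "numeric",
                 imbalanceRatio = "numeric", twilight = "list"))

#' Specification of a synthetic proteome pair
#'
#' Generation parameters for a deterministic pair of related proteomes with
#' a planted one-to-one ortholog subset, divergent random background, and
#' duplicated-then-diverged paralog "traps" (duplicates retained after a
#' whole-genome duplication that ortholog detectors tend to misclassify).
#' Generation is a pure function of the spec (including its seed).
#'
#' @slot nOrthologs planted one-to-one ortholog pairs.
#' @slot nBackground1,nBackground2 unrelated background proteins per
#'   proteome.
#' @slot nTraps duplicated ancestors: one derived copy in proteome 1, an
#'   extra-diverged paralogous copy in proteome 2, labelled negative.
#' @slot lengthRange ancestor length range (residues).
#' @slot mutationRate per-site substitution probability on each ortholog
#'   lineage branch.
#' @slot trapDivergence additional per-site substitution probability on the
#'   paralogous trap copy.
#' @slot seed RNG seed; same spec, same FASTA bytes.
#' @seealso \code{\link{syntheticPairSpec}}, \code{\link{generateProteomePair}},
#'   \code{\link{twilightSpec}}
#' @exportClass SyntheticPairSpec
setClass("SyntheticPairSpec",
  representation(nOrthologs = "integer", nBackground1 = "integer",
                 nBackground2 = "integer", nTraps = "integer",
                 lengthRange = "integer", mutationRate = "numeric",
                 trapDivergence = "numeric", seed = "integer"))

setValidity("SyntheticPairSpec", function(object) {
  counts <- c(object@nOrthologs, object@nBackground1, object@nBackground2,
              object@nTraps)
  if (any(counts < 0L)) return("all counts must be >= 0")
  if (length(object@lengthRange) != 2L ||
      any(object@lengthRange < 1L) ||
      object@lengthRange[1] > object@lengthRange[2])
    return("lengthRange must be an increasing pair of positive lengths")
  rates <- c(object@mutationRate, object@trapDivergence)
  if (any(rates < 0) || any(rates > 1)) return("rates must lie in [0, 1]")
  TRUE
})

#' Result of a pairwise protein alignment
#'
#' @slot score optimal alignment score in substitution-matrix units
#'   (local scores are floored at 0, the Smith-Waterman empty alignment).
#' @slot alignedX,alignedY gapped aligned strings of equal length.
#' @slot identityPct 100 * identical columns / aligned columns.
#' @slot mode \code{"global"} (Needleman-Wunsch) or \code{"local"}
#'   (Smith-Waterman).
#' @seealso \code{\link{alignPair}}
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(score = "numeric", alignedX = "character",
                 alignedY = "character", identityPct = "numeric",
                 mode = "character"))

setValidity("AlignmentResult", function(object) {
  if (nchar(object@alignedX) != nchar(object@alignedY))
    return("aligned strings must have equal length")
  if (object@identityPct < 0 || object@identityPct > 100)
    return("identityPct must lie in [0, 100]")
  if (object@mode == "local" && object@score < 0)
    return("local alignment scores are >= 0")
  TRUE
})
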