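# Alignment-based pairwise similarity: global/local alignment scores,
# physicochemical profiles of gap-free aligned regions, length similarity
# and percent identity (twilight-zone analysis).

#' Scoring scheme for pairwise alignment
#'
#' @param matrix substitution matrix name (any matrix shipped with
#'   \pkg{Biostrings}, e.g. \code{"BLOSUM62"}, \code{"PAM250"}) or a 20x20+
#'   numeric matrix in NCBI layout.
#' @param gapOpen,gapExtend positive gap penalties (affine gap model).
#' @return a list used by \code{\link{alignPair}} and
#'   \code{\link{buildFeatureMatrix}}.
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gapOpen = 10,
                          gapExtend = 0.5) {
  if (gapOpen <= 0 || gapExtend <= 0)
    stop("gap penalties must be positive", call. = FALSE)
  list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend)
}

.substMatrix <- function(scheme) {
  if (is.matrix(scheme$matrix)) return(scheme$matrix)
  get(data(list = scheme$matrix,
           package = "Biostrings",
           envir = environment()))
}

.alignSet <- function(xs, y, mode, scheme) {
  Biostrings::pairwiseAlignment(
    pattern = xs, subject = y,
    type = if (mode == "global") "global" else "local",
    substitutionMatrix = .substMatrix(scheme),
    gapOpening = scheme$gapOpen, gapExtension = scheme$gapExtend)
}

.identityFromAligned <- function(ax, ay) {
  cx <- strsplit(ax, "")[[1]]
  cy <- strsplit(ay, "")[[1]]
  if (!length(cx)) return(0)
  100 * sum(cx == cy & cx != "-") / length(cx)
}

#' Optimal pairwise protein alignment
#'
#' Needleman-Wunsch (global, with end gaps) or Smith-Waterman (local)
#' optimal alignment under an affine gap model. Local scores are floored at
#' 0 (the empty local alignment). The traceback is deterministic.
#'
#' @param x,y amino-acid sequences (strings or \code{AAString}).
#' @param mode \code{"global"} or \code{"local"}.
#' @param scheme a \code{\link{scoringScheme}}.
#' @return an \code{\link{AlignmentResult}}.
#' @export
#' @examples
#' alignPair("MKV", "MKV")
alignPair <- function(x, y, mode = c("global", "local"),
                      scheme = scoringScheme()) {
  mode <- match.arg(mode)
  x <- as.character(x); y <- as.character(y)
  if (!nchar(x) || !nchar(y))
    stop("both sequences must be non-empty", call. = FALSE)
  aln <- .alignSet(x, y, mode, scheme)
  sc <- Biostrings::score(aln)
  # pattern()/subject() return the gapped aligned region (the whole
  # sequences for global mode) without the slow flank-padding path
  ax <- as.character(Biostrings::pattern(aln))
  ay <- as.character(Biostrings::subject(aln))
  if (mode == "local" && sc < 0) {
    sc <- 0
    ax <- ""; ay <- ""
  }
  new("AlignmentResult", score = sc, alignedX = unname(ax),
      alignedY = unname(ay), identityPct = .identityFromAligned(ax, ay),
      mode = mode)
}

#' Physicochemical profile similarity of aligned sequences
#'
#' Over every gap-free run of an alignment, slides a window of width
#' \code{w} and compares the mean standardized Kyte-Doolittle hydropathy of
#' the two sides. The similarity is \code{1 - mean(|meanX - meanY|) / D},
#' where \code{D} is the range (max - min) of the standardized scale, so it
#' falls in [0, 1]; alignments with no gap-free run of length >= \code{w}
#' score 0.
#'
#' @param alignment an \code{\link{AlignmentResult}} (or a list with
#'   \code{alignedX}/\code{alignedY} strings).
#' @param w window width, one of 3, 5, 7.
#' @return similarity in [0, 1]; 1 for identical sequences.
#' @export
profileSimilarity <- function(alignment, w) {
  if (!w %in% c(3, 5, 7))
    stop("window width must be 3, 5 or 7", call. = FALSE)
  ax <- if (is(alignment, "AlignmentResult")) alignment@alignedX
        else alignment$alignedX
  ay <- if (is(alignment, "AlignmentResult")) alignment@alignedY
        else alignment$alignedY
  if (!nchar(ax)) return(0)
  .profileSims(utf8ToInt(ax), utf8ToInt(ay), ws = as.integer(w))[1]
}

#' Protein length similarity
#'
#' \code{min(|x|, |y|) / max(|x|, |y|)}: 1 for equal lengths, monotone
#' decreasing in the length difference.
#'
#' @param x,y amino-acid sequences.
#' @return value in (0, 1].
#' @export
lengthSimilarity <- function(x, y) {
  nx <- nchar(as.character(x)); ny <- nchar(as.character(y))
  if (!nx || !ny) stop("both sequences must be non-empty", call. = FALSE)
  min(nx, ny) / max(nx, ny)
}

#' Global-alignment percent identity
#'
#' Percent of identical columns in the optimal global alignment, the
#' quantity thresholded (default < 30) to delimit the twilight zone of
#' remote homology.
#'
#' @inheritParams alignPair
#' @return percentage in [0, 100].
#' @export
percentIdentity <- function(x, y, scheme = scoringScheme()) {
  alignPair(x, y, "global", scheme)@identityPct
}
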