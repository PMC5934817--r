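# Deterministic synthetic proteome-pair generator: planted one-to-one
# orthologs, random background, and duplicated-then-diverged paralog
# "traps" (the duplicates retained after a whole-genome duplication that
# ortholog detectors tend to misclassify).

#' Create a synthetic proteome-pair specification
#'
#' Defaults describe the desk-scale study condition used throughout the
#' package: 15 planted orthologs, 35 unrelated background proteins per
#' proteome and 5 paralog traps give a 55 x 55 = 3,025 pair universe with
#' an imbalance ratio of about 200, at per-branch mutation rate 0.2.
#'
#' @param nOrthologs planted one-to-one ortholog pairs.
#' @param nBackground1,nBackground2 unrelated background proteins.
#' @param nTraps duplicated ancestors whose extra-diverged paralogous copy
#'   lands in proteome 2 (labelled negative).
#' @param lengthRange ancestor length range in residues.
#' @param mutationRate per-site substitution probability per lineage.
#' @param trapDivergence additional per-site substitution probability of
#'   the paralogous copy.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @return a \code{\link{SyntheticPairSpec}}.
#' @export
syntheticPairSpec <- function(nOrthologs = 15L, nBackground1 = 35L,
                              nBackground2 = 35L, nTraps = 5L,
                              lengthRange = c(80L, 150L),
                              mutationRate = 0.2, trapDivergence = 0.3,
                              seed = 1L) {
  new("SyntheticPairSpec", nOrthologs = as.integer(nOrthologs),
      nBackground1 = as.integer(nBackground1),
      nBackground2 = as.integer(nBackground2), nTraps = as.integer(nTraps),
      lengthRange = as.integer(lengthRange),
      mutationRate = as.numeric(mutationRate),
      trapDivergence = as.numeric(trapDivergence), seed = as.integer(seed))
}

# substitution proposal distribution conditioned on the original residue:
# p(b | a) proportional to 2^(BLOSUM62[a, b] / 2) over b != a, so likely
# replacements are biochemically plausible and alignment scores degrade
# the way diverging homologs do.
.substProbs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    B <- get(data(list = "BLOSUM62", package = "Biostrings",
                  envir = environment()))[AA_ALPHABET20, AA_ALPHABET20]
    P <- 2^(B / 2)
    diag(P) <- 0
    cache <<- P / rowSums(P)
    cache
  }
})

.randomSeqInt <- function(len) sample.int(20L, len, replace = TRUE)

.mutateInt <- function(idx, rate) {
  if (rate <= 0) return(idx)
  hit <- which(runif(length(idx)) < rate)
  if (!length(hit)) return(idx)
  P <- .substProbs()
  idx[hit] <- vapply(idx[hit], function(a)
    sample.int(20L, 1L, prob = P[a, ]), integer(1))
  idx
}

# +/-10% length jitter so global alignments exercise end gaps even though
# no explicit indel process is modelled; an undiverged copy (rate 0) is
# returned unchanged, so zero-rate orthologs stay 100% identical
.jitterLength <- function(idx, rate, frac = 0.1) {
  if (rate <= 0) return(idx)
  n <- length(idx)
  target <- max(1L, round(n * runif(1, 1 - frac, 1 + frac)))
  if (target <= n) idx[seq_len(target)]
  else c(idx, .randomSeqInt(target - n))
}

.intToSeq <- function(idx) paste(AA_ALPHABET20[idx], collapse = "")

#' Generate a synthetic proteome pair with known truth
#'
#' Each planted ortholog pair derives two copies of a common ancestor by
#' independent per-site substitutions (BLOSUM62-conditional replacement
#' residues) at \code{mutationRate} on each branch, plus a \eqn{\pm}10\%
#' length jitter; background proteins are independent uniform-random
#' sequences; each trap duplicates an ancestor, places one derived copy in
#' proteome 1 and an extra-diverged paralogous copy in proteome 2, and is
#' labelled negative. Identifiers encode the ground truth
#' (\code{ort}/\code{trap}/\code{bg} prefixes) for test introspection.
#'
#' @param spec a \code{\link{SyntheticPairSpec}}.
#' @return list with \code{p1}, \code{p2} (named \code{AAStringSet}s),
#'   \code{gold} (\code{\link{GoldLabels}}: the planted ortholog pairs) and
#'   \code{trapPairs} (data.frame of the planted negative paralog pairs).
#' @export
#' @examples
#' gp <- generateProteomePair(syntheticPairSpec(nOrthologs = 2,
#'   nBackground1 = 3, nBackground2 = 3, nTraps = 1, seed = 7))
#' names(gp$p1)
generateProteomePair <- function(spec) {
  stopifnot(is(spec, "SyntheticPairSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    lens <- function(k) sample(spec@lengthRange[1]:spec@lengthRange[2], k,
                               replace = TRUE)
    s1 <- character(0); s2 <- character(0)
    id1 <- character(0); id2 <- character(0)
    gold <- data.frame(id1 = character(0), id2 = character(0),
                       stringsAsFactors = FALSE)
    traps <- data.frame(id1 = character(0), id2 = character(0),
                        stringsAsFactors = FALSE)
    if (spec@nOrthologs > 0L) {
      for (i in seq_len(spec@nOrthologs)) {
        anc <- .randomSeqInt(lens(1L))
        a <- .jitterLength(.mutateInt(anc, spec@mutationRate),
                           spec@mutationRate)
        b <- .jitterLength(.mutateInt(anc, spec@mutationRate),
                           spec@mutationRate)
        id1 <- c(id1, sprintf("ort%03d_p1", i))
        id2 <- c(id2, sprintf("ort%03d_p2", i))
        s1 <- c(s1, .intToSeq(a)); s2 <- c(s2, .intToSeq(b))
      }
      gold <- data.frame(id1 = sprintf("ort%03d_p1", seq_len(spec@nOrthologs)),
                         id2 = sprintf("ort%03d_p2", seq_len(spec@nOrthologs)),
                         stringsAsFactors = FALSE)
    }
    if (spec@nTraps > 0L) {
      for (i in seq_len(spec@nTraps)) {
        anc <- .randomSeqInt(lens(1L))
        a <- .jitterLength(.mutateInt(anc, spec@mutationRate),
                           spec@mutationRate)
        b <- .mutateInt(anc, spec@mutationRate)
        b <- .jitterLength(.mutateInt(b, spec@trapDivergence),
                           spec@mutationRate + spec@trapDivergence)
        id1 <- c(id1, sprintf("trap%03d_p1", i))
        id2 <- c(id2, sprintf("trap%03d_p2", i))
        s1 <- c(s1, .intToSeq(a)); s2 <- c(s2, .intToSeq(b))
      }
      traps <- data.frame(id1 = sprintf("trap%03d_p1", seq_len(spec@nTraps)),
                          id2 = sprintf("trap%03d_p2", seq_len(spec@nTraps)),
                          stringsAsFactors = FALSE)
    }
    if (spec@nBackground1 > 0L) {
      for (i in seq_len(spec@nBackground1)) {
        id1 <- c(id1, sprintf("bg%03d_p1", i))
        s1 <- c(s1, .intToSeq(.randomSeqInt(lens(1L))))
      }
    }
    if (spec@nBackground2 > 0L) {
      for (i in seq_len(spec@nBackground2)) {
        id2 <- c(id2, sprintf("bg%03d_p2", i))
        s2 <- c(s2, .intToSeq(.randomSeqInt(lens(1L))))
      }
    }
    p1 <- Biostrings::AAStringSet(setNames(s1, id1))
    p2 <- Biostrings::AAStringSet(setNames(s2, id2))
    list(p1 = p1, p2 = p2, gold = goldLabels(gold, id1, id2),
         trapPairs = traps)
  })
}

#' Calibrate a spec into the twilight zone
#'
#' Bisects the mutation rate so the median global-alignment percent
#' identity of the planted ortholog pairs falls to \code{targetIdentity}
#' (default 25, safely below the 30\% twilight threshold). Identity is
#' monotone non-increasing in the mutation rate, so bisection converges;
#' the returned spec differs from the input only in its mutation rate.
#'
#' @param spec a \code{\link{SyntheticPairSpec}}.
#' @param targetIdentity median ortholog percent identity to aim for.
#' @param nProbe ortholog pairs simulated per bisection step.
#' @param iterations bisection steps.
#' @param scheme alignment \code{\link{scoringScheme}}.
#' @return the calibrated \code{SyntheticPairSpec}.
#' @export
twilightSpec <- function(spec, targetIdentity = 25, nProbe = 12L,
                         iterations = 8L, scheme = scoringScheme()) {
  stopifnot(is(spec, "SyntheticPairSpec"))
  medianIdentity <- function(rate) {
    probe <- spec
    probe@mutationRate <- rate
    probe@nOrthologs <- as.integer(nProbe)
    probe@nBackground1 <- 0L; probe@nBackground2 <- 0L
    probe@nTraps <- 0L
    gp <- generateProteomePair(probe)
    ids <- stats::median(vapply(seq_along(gp$p1), function(i)
      percentIdentity(as.character(gp$p1[[i]]), as.character(gp$p2[[i]]),
                      scheme), numeric(1)))
    ids
  }
  lo <- 0; hi <- 0.98
  for (k in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    if (medianIdentity(mid) > targetIdentity) lo <- mid else hi <- mid
  }
  out <- spec
  out@mutationRate <- hi
  out
}
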