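# Significance-gated Pearson similarity and assembly of the 29-column
# pairwise feature matrix.

#' The named feature columns of a configuration
#'
#' The combined configuration yields exactly 29 columns, partitioned into
#' 5 alignment-based (\code{nw}, \code{sw}, \code{profile3/5/7}) and 24
#' alignment-free columns (protein length similarity is counted with the
#' alignment-free block since it needs no alignment).
#'
#' @param set \code{"combined"}, \code{"ab"} (alignment-based) or
#'   \code{"af"} (alignment-free).
#' @return character vector of column names in matrix order.
#' @export
#' @examples
#' length(featureColumnNames())       # 29
#' length(featureColumnNames("ab"))   # 5
featureColumnNames <- function(set = c("combined", "ab", "af")) {
  set <- match.arg(set)
  ab <- c("nw", "sw", "profile3", "profile5", "profile7")
  af <- c("aac", "Auto_Geary", "Auto_Moran", "Auto_Total",
          "CTD", "CTD_C", "CTD_D", "CTD_T", "fcm",
          "2-mers", "2-mers_dc1", "2-mers_dc2", "2-mers_dc3",
          "3-mers", "3-mers_dc1", "3-mers_dc2", "3-mers_dc3",
          "length", "nandy", "pseaa3", "pseaa4", "pseaa10",
          "QSO_w01_maxlag30", "QSOCN_maxlag30")
  combined <- c("nw", "sw", "profile3", "profile5", "profile7",
                "aac", "Auto_Geary", "Auto_Moran", "Auto_Total",
                "CTD", "CTD_C", "CTD_D", "CTD_T", "fcm",
                "2-mers", "2-mers_dc1", "2-mers_dc2", "2-mers_dc3",
                "3-mers", "3-mers_dc1", "3-mers_dc2", "3-mers_dc3",
                "length", "nandy", "pseaa3", "pseaa4", "pseaa10",
                "QSO_w01_maxlag30", "QSOCN_maxlag30")
  switch(set, combined = combined, ab = ab, af = af)
}

# spaced-word pattern sets of the spaced k-mer feature columns
.SPACED_PATTERNS <- list(
  `2-mers_dc1` = "101",
  `2-mers_dc2` = "1001",
  `2-mers_dc3` = "10001",
  `3-mers_dc1` = c("1101", "1011"),
  `3-mers_dc2` = c("10011", "10101", "11001"),
  `3-mers_dc3` = c("100011", "110001", "101001", "100101"))

#' Configuration of the feature matrix builder
#'
#' @param scheme alignment \code{\link{scoringScheme}}.
#' @param alpha significance level gating the Pearson similarity.
#' @param autocorrMaxlag,qsoMaxlag largest lags of the autocorrelation and
#'   quasi-sequence-order descriptors.
#' @param qsoWeight,pseaaWeight weighting factors of the QSO coupling block
#'   and the pseudo-composition sequence-order block.
#' @param momentsOrder number of spectral moments of the graphical maps.
#' @return named list of parameters (stored as matrix provenance).
#' @export
featureConfig <- function(scheme = scoringScheme(), alpha = 0.05,
                          autocorrMaxlag = 30L, qsoMaxlag = 30L,
                          qsoWeight = 0.1, pseaaWeight = 0.05,
                          momentsOrder = 15L) {
  list(scheme = scheme, alpha = alpha,
       autocorrMaxlag = as.integer(autocorrMaxlag),
       qsoMaxlag = as.integer(qsoMaxlag), qsoWeight = qsoWeight,
       pseaaWeight = pseaaWeight, momentsOrder = as.integer(momentsOrder))
}

#' Significance-gated Pearson similarity of two descriptor vectors
#'
#' The Pearson correlation \eqn{r} of the two vectors is returned when it
#' is significant (two-sided t test, \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on
#' \eqn{n-2} degrees of freedom, p-value \eqn{\le} \code{alpha}) and 0
#' otherwise; a zero-variance vector also gives 0 (no evidence, no
#' similarity). Negative significant correlations are returned as-is.
#'
#' @param vx,vy descriptor vectors of the same family, parameters and
#'   dimension \eqn{n \ge 3}.
#' @param alpha significance level (default 0.05).
#' @return value in [-1, 1].
#' @export
#' @examples
#' pearsonGatedSimilarity(aaComposition("MKVL"), aaComposition("MKVL"))
pearsonGatedSimilarity <- function(vx, vy, alpha = 0.05) {
  fx <- attr(vx, "family"); fy <- attr(vy, "family")
  if (!is.null(fx) && !is.null(fy)) {
    if (!identical(fx, fy))
      stop("descriptor families differ: ", fx, " vs ", fy, call. = FALSE)
    if (!identical(attr(vx, "params"), attr(vy, "params")))
      stop("descriptor parameters differ", call. = FALSE)
  }
  if (length(vx) != length(vy))
    stop("descriptor dimensions differ: ", length(vx), " vs ", length(vy),
         call. = FALSE)
  n <- length(vx)
  if (n < 3L) stop("need dimension >= 3 for the significance test",
                   call. = FALSE)
  if (sd(vx) == 0 || sd(vy) == 0) return(0)
  r <- cor(as.numeric(vx), as.numeric(vy))
  if (.pearsonPValue(r, n) <= alpha) r else 0
}

.pearsonPValue <- function(r, n) {
  r2 <- pmin(r^2, 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r2, 0))  # Inf when |r| = 1
  2 * pt(tt, df = n - 2, lower.tail = FALSE)
}

# Gated correlation of every column of X against every column of Y.
# NA columns (descriptor undefined for that protein) and zero-variance
# columns give 0.
.gatedCorMatrix <- function(X, Y, alpha) {
  n <- nrow(X)
  out <- matrix(0, ncol(X), ncol(Y))
  ok1 <- !is.na(colSums(X)) & matrixStatsSd(X) > 0
  ok2 <- !is.na(colSums(Y)) & matrixStatsSd(Y) > 0
  if (!any(ok1) || !any(ok2)) return(out)
  R <- cor(X[, ok1, drop = FALSE], Y[, ok2, drop = FALSE])
  P <- .pearsonPValue(R, n)
  R[P > alpha] <- 0
  out[ok1, ok2] <- R
  out
}

matrixStatsSd <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * m^2, 0) / (n - 1))
}

#' Max-normalize a feature column
#'
#' Divides each value by the maximum absolute value of the column, so the
#' normalized column has maximum absolute value 1; signs are preserved and
#' an all-zero column is returned unchanged.
#'
#' @param column numeric vector of finite values.
#' @return normalized numeric vector.
#' @export
#' @examples
#' normalizeByMax(c(2, 4, 8))
#' normalizeByMax(c(-1, 2))
normalizeByMax <- function(column) {
  if (any(!is.finite(column))) stop("values must be finite", call. = FALSE)
  m <- max(abs(column))
  if (m == 0) column else column / m
}

# all alignment-free descriptor families of one sequence, sharing the
# expensive passes (one autocorrelation sweep feeds the three Auto_*
# features, one CTD sweep feeds the four CTD features); a family whose
# precondition fails (e.g. sequence shorter than a maxlag) yields NA
.afFamilyVectors <- function(s, config) {
  tc <- function(expr) tryCatch(unname(as.numeric(expr)),
                                error = function(e) NA_real_)
  out <- list(aac = tc(aaComposition(s)))
  idx <- seqToInt(s)
  n <- length(idx)
  if (n > config$autocorrMaxlag) {
    acs <- .autocorrVectors(idx, config$autocorrMaxlag)
    tot <- unname(c(acs$moreau_broto, acs$moran, acs$geary))
    m <- max(abs(tot))
    if (m > 0) tot <- tot / m
    out$Auto_Geary <- unname(acs$geary)
    out$Auto_Moran <- unname(acs$moran)
    out$Auto_Total <- tot
  } else {
    out$Auto_Geary <- out$Auto_Moran <- out$Auto_Total <- NA_real_
  }
  if (n >= 2L) {
    parts <- .ctdParts(idx)
    out$CTD <- unname(c(parts$C, parts$T, parts$D))
    out$CTD_C <- unname(parts$C)
    out$CTD_D <- unname(parts$D)
    out$CTD_T <- unname(parts$T)
  } else {
    parts <- .ctdParts(idx, withT = FALSE)
    out$CTD <- out$CTD_T <- NA_real_
    out$CTD_C <- unname(parts$C)
    out$CTD_D <- unname(parts$D)
  }
  out$fcm <- tc(graphicalMoments(s, "four_colour", config$momentsOrder))
  out$`2-mers` <- tc(wordFrequencies(s, k = 2))
  for (f in c("2-mers_dc1", "2-mers_dc2", "2-mers_dc3",
              "3-mers_dc1", "3-mers_dc2", "3-mers_dc3"))
    out[[f]] <- tc(wordFrequencies(s, pattern = .SPACED_PATTERNS[[f]]))
  out$`3-mers` <- tc(wordFrequencies(s, k = 3))
  out$nandy <- tc(graphicalMoments(s, "nandy", config$momentsOrder))
  out$pseaa3 <- tc(pseudoAAComposition(s, 3L, config$pseaaWeight))
  out$pseaa4 <- tc(pseudoAAComposition(s, 4L, config$pseaaWeight))
  out$pseaa10 <- tc(pseudoAAComposition(s, 10L, config$pseaaWeight))
  out$QSO_w01_maxlag30 <- tc(qsoDescriptor(s, config$qsoMaxlag,
                                           config$qsoWeight,
                                           "schneider_wrede"))
  out$QSOCN_maxlag30 <- tc(qsoDescriptor(s, config$qsoMaxlag,
                                         config$qsoWeight, "grantham"))
  out
}

# dim x n matrix of one family over the per-sequence vector lists;
# undefined descriptors give NA columns
.famMatrix <- function(vecLists, fam) {
  cols <- lapply(vecLists, `[[`, fam)
  d <- max(lengths(cols))
  m <- vapply(cols, function(v) if (length(v) == d) v else rep(NA_real_, d),
              numeric(d))
  matrix(m, nrow = d)
}

#' Build the pairwise feature matrix
#'
#' Computes, for every candidate pair, the alignment-based similarities
#' (raw global/local optimal scores, physicochemical profile at windows 3,
#' 5, 7), the length similarity, and the significance-gated Pearson
#' similarities of the alignment-free descriptor families, then
#' max-normalizes every column. Pairs for which a descriptor is undefined
#' (e.g. a protein shorter than a maxlag) contribute 0 for that feature.
#' Deterministic given proteomes, pairs and configuration.
#'
#' @param p1,p2 sanitized proteomes (named \code{AAStringSet}s).
#' @param pairs data.frame of candidate pairs (columns \code{id1},
#'   \code{id2}); default: all \code{length(p1) * length(p2)} pairs in
#'   lexicographic order.
#' @param labels a \code{\link{GoldLabels}} object or an integer 0/1 vector
#'   aligned with \code{pairs}; omit for unlabelled matrices.
#' @param set \code{"combined"} (29 features), \code{"ab"} (5) or
#'   \code{"af"} (24).
#' @param config a \code{\link{featureConfig}}.
#' @param verbose report descriptor failures downgraded to 0.
#' @return a \code{\link{PairFeatures}} object; when alignments were
#'   computed the pair table also carries \code{identity_pct}.
#' @export
buildFeatureMatrix <- function(p1, p2, pairs = NULL, labels = NULL,
                               set = c("combined", "ab", "af"),
                               config = featureConfig(), verbose = FALSE) {
  set <- match.arg(set)
  if (is.null(pairs)) pairs <- enumeratePairs(p1, p2)
  cols <- featureColumnNames(set)
  u1 <- unique(pairs$id1); u2 <- unique(pairs$id2)
  if (anyNA(match(u1, names(p1))) || anyNA(match(u2, names(p2))))
    stop("pair table references ids absent from the proteomes",
         call. = FALSE)
  s1 <- as.character(p1[u1]); s2 <- as.character(p2[u2])
  n1 <- length(s1); n2 <- length(s2)
  i1 <- match(pairs$id1, u1); i2 <- match(pairs$id2, u2)
  flat <- (i2 - 1L) * n1 + i1   # index into n1 x n2 matrices
  feat <- matrix(0, nrow(pairs), length(cols),
                 dimnames = list(NULL, cols))
  identity <- rep(NA_real_, nrow(pairs))

  need_ab <- set %in% c("combined", "ab")
  if (need_ab) {
    # one vectorized alignment call over the requested pairs
    pat <- Biostrings::AAStringSet(s1[i1])
    sub <- Biostrings::AAStringSet(s2[i2])
    subst <- .substMatrix(config$scheme)
    g <- Biostrings::pairwiseAlignment(
      pat, sub, type = "global", substitutionMatrix = subst,
      gapOpening = config$scheme$gapOpen,
      gapExtension = config$scheme$gapExtend)
    feat[, "nw"] <- Biostrings::score(g)
    feat[, "sw"] <- pmax(Biostrings::pairwiseAlignment(
      pat, sub, type = "local", substitutionMatrix = subst,
      gapOpening = config$scheme$gapOpen,
      gapExtension = config$scheme$gapExtend, scoreOnly = TRUE), 0)
    ax <- as.character(Biostrings::pattern(g))
    ay <- as.character(Biostrings::subject(g))
    prof <- matrix(0, nrow(pairs), 3L)
    for (i in seq_len(nrow(pairs))) {
      bx <- utf8ToInt(ax[i])
      by <- utf8ToInt(ay[i])
      identity[i] <- 100 * sum(bx == by & bx != .GAP_BYTE) / length(bx)
      prof[i, ] <- .profileSims(bx, by)
    }
    feat[, "profile3"] <- prof[, 1]
    feat[, "profile5"] <- prof[, 2]
    feat[, "profile7"] <- prof[, 3]
  }

  if (set %in% c("combined", "af")) {
    w1 <- nchar(s1); w2 <- nchar(s2)
    lm <- outer(w1, w2, pmin) / outer(w1, w2, pmax)
    feat[, "length"] <- lm[flat]
    lists1 <- lapply(s1, .afFamilyVectors, config = config)
    lists2 <- lapply(s2, .afFamilyVectors, config = config)
    for (fam in setdiff(featureColumnNames("af"), "length")) {
      X <- .famMatrix(lists1, fam)
      Y <- .famMatrix(lists2, fam)
      n_fail <- sum(is.na(X[1, ])) + sum(is.na(Y[1, ]))
      if (n_fail && verbose)
        message("feature '", fam, "': descriptor undefined for ", n_fail,
                " protein(s); affected pairs set to 0")
      feat[, fam] <- .gatedCorMatrix(X, Y, config$alpha)[flat]
    }
  }

  feat <- apply(feat, 2L, normalizeByMax)
  if (!is.matrix(feat))  # single pair
    feat <- matrix(feat, nrow = 1L, dimnames = list(NULL, cols))
  pairs_out <- pairs[, c("id1", "id2")]
  if (need_ab) pairs_out$identity_pct <- identity
  lab <- integer(0)
  if (!is.null(labels)) {
    lab <- if (is(labels, "GoldLabels")) labelPairs(labels, pairs)
           else as.integer(labels)
  }
  new("PairFeatures", pairs = pairs_out, features = feat, label = lab,
      params = list(set = set, config = config))
}

# profile similarity at windows 3/5/7 from aligned character codes
.profileSims <- function(bx, by, ws = c(3L, 5L, 7L)) {
  D <- .PROFILE_RANGE
  ungapped <- bx != .GAP_BYTE & by != .GAP_BYTE
  out <- numeric(length(ws))
  if (!any(ungapped)) return(out)
  runs <- rle(ungapped)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  segs <- lapply(keep, function(r) {
    seg <- starts[r]:ends[r]
    list(px = .HYD_BY_BYTE[bx[seg]],
         py = .HYD_BY_BYTE[by[seg]])
  })
  for (wi in seq_along(ws)) {
    w <- ws[wi]
    diffs <- numeric(0)
    for (sg in segs) {
      L <- length(sg$px)
      if (L < w) next
      csx <- c(0, cumsum(sg$px)); csy <- c(0, cumsum(sg$py))
      nwin <- L - w + 1L
      mx <- (csx[(w + 1):(L + 1)] - csx[1:nwin]) / w
      my <- (csy[(w + 1):(L + 1)] - csy[1:nwin]) / w
      diffs <- c(diffs, abs(mx - my))
    }
    out[wi] <- if (length(diffs)) min(max(1 - mean(diffs) / D, 0), 1) else 0
  }
  out
}
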