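# Alignment-free per-protein descriptor vectors. Each family maps a
# sanitized amino-acid sequence to a fixed-length numeric vector whose
# dimension depends only on the family and its parameters, never on the
# sequence. Pairs of vectors are later compared with the significance-gated
# Pearson similarity.

descriptorVector <- function(values, family, params = list()) {
  if (any(!is.finite(values)))
    stop("descriptor produced non-finite values", call. = FALSE)
  structure(values, family = family, params = params)
}

#' Amino acid composition
#'
#' Fraction of each canonical residue in the protein, residue order
#' \code{ACDEFGHIKLMNPQRSTVWY}.
#'
#' @param seq sanitized amino-acid sequence (single string).
#' @return named 20-vector summing to 1, with attributes \code{family} and
#'   \code{params}.
#' @export
#' @examples
#' aaComposition("ACAC")[c("A", "C")]
aaComposition <- function(seq) {
  idx <- seqToInt(seq)
  v <- tabulate(idx, 20L) / length(idx)
  names(v) <- AA_ALPHABET20
  descriptorVector(v, "aac")
}

#' Pseudo amino acid composition (type 1)
#'
#' Chou's type-1 pseudo amino acid composition: the 20 composition entries
#' are augmented with \code{lambda} sequence-order correlation factors
#' \eqn{\theta_j = \frac{1}{n-j}\sum_i \Theta(R_i, R_{i+j})}, where
#' \eqn{\Theta} averages the squared differences of three standardized
#' per-residue scales (hydrophobicity, hydrophilicity, side-chain mass).
#' The whole \code{20 + lambda} vector is normalized to sum to 1 with the
#' correlation block weighted by \code{w}.
#'
#' @param seq sanitized amino-acid sequence.
#' @param lambda topological distance up to which sequence-order correlation
#'   is collected; must be smaller than the protein length.
#' @param w weight of the sequence-order block (default 0.05).
#' @return named \code{(20 + lambda)}-vector summing to 1.
#' @export
pseudoAAComposition <- function(seq, lambda, w = 0.05) {
  idx <- seqToInt(seq)
  n <- length(idx)
  lambda <- as.integer(lambda)
  if (n <= lambda)
    stop("pseudo amino acid composition needs lambda < protein length (",
         lambda, " >= ", n, ")", call. = FALSE)
  f <- tabulate(idx, 20L) / n
  theta <- numeric(lambda)
  if (lambda > 0L) {
    props <- scale(cbind(.KD_HYDROPHOBICITY, .HW_HYDROPHILICITY,
                         .SIDE_CHAIN_MASS))
    pm <- props[idx, , drop = FALSE]
    for (j in seq_len(lambda)) {
      d <- pm[1:(n - j), , drop = FALSE] - pm[(1 + j):n, , drop = FALSE]
      theta[j] <- mean(rowMeans(d^2))
    }
  }
  denom <- sum(f) + w * sum(theta)
  v <- c(f, w * theta) / denom
  names(v) <- c(AA_ALPHABET20,
                if (lambda > 0L) paste0("theta", seq_len(lambda)))
  descriptorVector(v, "pseaa", list(lambda = lambda, w = w))
}

kmerNames <- function(k) {
  words <- AA_ALPHABET20
  if (k > 1L) for (i in 2:k)
    words <- as.vector(t(outer(words, AA_ALPHABET20, paste0)))
  words
}

#' k-mer and spaced-word frequencies
#'
#' Counts the words read through a binary match/don't-care pattern slid
#' along the sequence (\code{1} = match position contributing a letter,
#' \code{0} = wildcard). \code{pattern = "contiguous"} is the ordinary
#' k-mer count. Several patterns for one feature (e.g. \code{c("1101",
#' "1011")}) are pooled into one shared vector, window totals summed across
#' patterns.
#'
#' @param seq sanitized amino-acid sequence.
#' @param k word size (match positions); required for
#'   \code{pattern = "contiguous"}, otherwise inferred from the patterns.
#' @param pattern \code{"contiguous"} or a character vector of binary
#'   patterns, each starting and ending with \code{1} and containing the
#'   same number of \code{1}s.
#' @return named \code{20^k}-vector of word frequencies summing to 1.
#' @export
#' @examples
#' wordFrequencies("ACAC", k = 2)[c("AC", "CA")]
#' wordFrequencies("ACAC", pattern = "101")[c("AA", "CC")]
wordFrequencies <- function(seq, k = NULL, pattern = "contiguous") {
  idx <- seqToInt(seq)
  n <- length(idx)
  if (identical(pattern, "contiguous")) {
    if (is.null(k)) stop("'k' is required for contiguous k-mers",
                         call. = FALSE)
    pattern <- strrep("1", k)
  }
  pats <- lapply(pattern, function(p) {
    ch <- strsplit(p, "")[[1]]
    if (!all(ch %in% c("0", "1")))
      stop("patterns are binary strings", call. = FALSE)
    if (ch[1] != "1" || ch[length(ch)] != "1")
      stop("patterns must start and end with a match position",
           call. = FALSE)
    which(ch == "1")
  })
  ks <- lengths(pats)
  if (length(unique(ks)) != 1L)
    stop("all patterns must have the same number of match positions",
         call. = FALSE)
  if (!is.null(k) && ks[1] != k)
    stop("pattern match positions disagree with 'k'", call. = FALSE)
  k <- ks[1]
  counts <- numeric(20^k)
  total <- 0L
  for (mp in pats) {
    L <- mp[length(mp)]
    nw <- n - L + 1L
    if (nw < 1L) next
    starts <- seq_len(nw)
    code <- integer(nw)
    for (j in mp) code <- code * 20L + (idx[starts + j - 1L] - 1L)
    counts <- counts + tabulate(code + 1L, 20^k)
    total <- total + nw
  }
  if (total == 0L)
    stop("sequence shorter than every pattern: zero windows", call. = FALSE)
  v <- counts / total
  names(v) <- kmerNames(k)
  descriptorVector(v, "word_frequencies",
                   list(k = k, pattern = pattern))
}

#' Physicochemical autocorrelation descriptors
#'
#' Moreau-Broto, Moran and Geary autocorrelation of the seven standardized
#' per-residue scales of \code{\link{aaPropertyTable}} at lags 1..maxlag.
#' \code{"total"} concatenates the three methods (Moreau-Broto, Moran,
#' Geary) and rescales the concatenation to unit maximum absolute value.
#' An attribute with zero variance along the sequence contributes zeros.
#'
#' @param seq sanitized amino-acid sequence, longer than \code{maxlag}.
#' @param method one of \code{"geary"}, \code{"moran"},
#'   \code{"moreau_broto"}, \code{"total"}.
#' @param maxlag largest topological distance considered (default 30).
#' @return named vector of dimension \code{7 * maxlag} (methods) or
#'   \code{21 * maxlag} (total).
#' @export
aaAutocorrelation <- function(seq,
                              method = c("geary", "moran", "moreau_broto",
                                         "total"),
                              maxlag = 30L) {
  method <- match.arg(method)
  idx <- seqToInt(seq)
  n <- length(idx)
  maxlag <- as.integer(maxlag)
  if (n <= maxlag)
    stop("autocorrelation needs protein length > maxlag (", n, " <= ",
         maxlag, ")", call. = FALSE)
  acs <- .autocorrVectors(idx, maxlag)
  if (method == "total") {
    v <- c(moreau_broto = acs$moreau_broto, moran = acs$moran,
           geary = acs$geary)
    m <- max(abs(v))
    if (m > 0) v <- v / m
  } else {
    v <- acs[[method]]
  }
  descriptorVector(v, paste0("autocorrelation_", method),
                   list(maxlag = maxlag))
}

# all three autocorrelation series in one pass over the sequence
.autocorrVectors <- function(idx, maxlag) {
  n <- length(idx)
  props <- aaPropertyTable(standardized = TRUE)
  na <- ncol(props)
  mb <- mo <- ge <- numeric(na * maxlag)
  nm <- character(na * maxlag)
  for (a in seq_len(na)) {
    p <- props[idx, a]
    pc <- p - mean(p)
    ss <- sum(pc^2)
    at <- (a - 1L) * maxlag
    nm[at + seq_len(maxlag)] <-
      paste0(colnames(props)[a], ".lag", seq_len(maxlag))
    if (ss == 0) next  # degenerate: property constant on this sequence
    for (d in seq_len(maxlag)) {
      i <- 1:(n - d)
      mb[at + d] <- sum(p[i] * p[i + d]) / (n - d)
      mo[at + d] <- (sum(pc[i] * pc[i + d]) / (n - d)) / (ss / n)
      ge[at + d] <- (sum((p[i] - p[i + d])^2) / (2 * (n - d))) /
        (ss / (n - 1))
    }
  }
  names(mb) <- names(mo) <- names(ge) <- nm
  list(moreau_broto = mb, moran = mo, geary = ge)
}

#' Composition / Transition / Distribution (CTD) descriptors
#'
#' Each of seven physicochemical attributes encodes the sequence into three
#' classes. Composition (C): the class fractions (3 per attribute).
#' Transition (T): the frequencies of adjacent class changes 1<->2, 1<->3,
#' 2<->3 with denominator \code{length - 1}. Distribution (D): for each
#' class, the sequence positions at which its first, 25\%, 50\%, 75\% and
#' last occurrence fall, as fractions of the length (an absent class gives
#' zeros). \code{"total"} is the concatenation C, T, D (dimension 147).
#'
#' @param seq sanitized amino-acid sequence (length >= 2 for T and total).
#' @param part \code{"total"}, \code{"C"}, \code{"T"} or \code{"D"}.
#' @return named vector of dimension 21 (C), 21 (T), 105 (D) or 147.
#' @export
ctdDescriptor <- function(seq, part = c("total", "C", "T", "D")) {
  part <- match.arg(part)
  idx <- seqToInt(seq)
  n <- length(idx)
  if (part %in% c("T", "total") && n < 2L)
    stop("transition descriptors need at least 2 residues", call. = FALSE)
  parts <- .ctdParts(idx, withT = part %in% c("T", "total"))
  v <- switch(part,
              C = parts$C, T = parts$T, D = parts$D,
              total = c(parts$C, parts$T, parts$D))
  descriptorVector(v, paste0("ctd_", part))
}

.ctdParts <- function(idx, withT = TRUE) {
  n <- length(idx)
  cls_idx <- .ctdClassIndex()
  attrs <- colnames(cls_idx)
  C <- Tr <- D <- numeric(0)
  for (a in attrs) {
    cls <- cls_idx[idx, a]
    v <- tabulate(cls, 3L) / n
    names(v) <- paste0(a, ".C", 1:3)
    C <- c(C, v)
    if (withT) {
      from <- cls[-n]; to <- cls[-1]
      pair <- pmin(from, to) * 10L + pmax(from, to)
      v <- c(sum(pair == 12L), sum(pair == 13L), sum(pair == 23L)) / (n - 1)
      names(v) <- paste0(a, ".T", c("12", "13", "23"))
      Tr <- c(Tr, v)
    }
    for (k in 1:3) {
      pos <- which(cls == k)
      m <- length(pos)
      v <- if (m == 0L) numeric(5L) else
        pos[c(1L, ceiling(0.25 * m), ceiling(0.5 * m),
              ceiling(0.75 * m), m)] / n
      names(v) <- paste0(a, ".D", k, ".", c("first", "25", "50", "75",
                                            "100"))
      D <- c(D, v)
    }
  }
  list(C = C, T = Tr, D = D)
}

#' Quasi-sequence-order (QSO) descriptors
#'
#' Combines composition with sequence-order coupling numbers
#' \eqn{\tau_d = \sum_i d(R_i, R_{i+d})^2} for \code{d = 1..maxlag}, where
#' \eqn{d(\cdot,\cdot)} is a residue-pair physicochemical distance
#' (\code{\link{aaDistanceMatrix}}). The first 20 entries are
#' \eqn{f_r / (\sum f + w \sum \tau)}, the last \code{maxlag} entries
#' \eqn{w \tau_d / (\sum f + w \sum \tau)}; the whole vector sums to 1.
#'
#' @param seq sanitized amino-acid sequence, longer than \code{maxlag}.
#' @param maxlag largest coupling distance (default 30).
#' @param w weighting factor of the coupling block (default 0.1).
#' @param dist residue-pair distance matrix to use.
#' @return named \code{(20 + maxlag)}-vector summing to 1.
#' @export
qsoDescriptor <- function(seq, maxlag = 30L, w = 0.1,
                          dist = c("schneider_wrede", "grantham")) {
  dist <- match.arg(dist)
  idx <- seqToInt(seq)
  n <- length(idx)
  maxlag <- as.integer(maxlag)
  if (n <= maxlag)
    stop("quasi-sequence-order needs protein length > maxlag (", n, " <= ",
         maxlag, ")", call. = FALSE)
  D <- aaDistanceMatrix(dist)
  tau <- vapply(seq_len(maxlag), function(d) {
    i <- 1:(n - d)
    sum(D[cbind(idx[i], idx[i + d])]^2)
  }, numeric(1))
  f <- tabulate(idx, 20L) / n
  denom <- sum(f) + w * sum(tau)
  v <- c(f, w * tau) / denom
  names(v) <- c(AA_ALPHABET20, paste0("tau", seq_len(maxlag)))
  descriptorVector(v, "qso", list(maxlag = maxlag, w = w, dist = dist))
}

# 4-class physicochemical grouping shared by the graphical maps:
# 1 nonpolar, 2 polar-uncharged, 3 acidic, 4 basic
.graphClass4 <- function(idx) {
  groups <- c(A = 1, V = 1, L = 1, I = 1, P = 1, F = 1, M = 1, W = 1, G = 1,
              S = 2, T = 2, C = 2, Y = 2, N = 2, Q = 2,
              D = 3, E = 3, K = 4, R = 4, H = 4)
  unname(groups[AA_ALPHABET20][idx])
}

#' Spectral moments of graphical sequence maps
#'
#' Embeds the protein in a 2D map, builds the adjacency matrix of the
#' resulting graph, row-normalizes it where row sums are nonzero, and
#' returns the spectral moment series \eqn{\mu_k = tr(A^k)/n} for
#' \code{k = 1..order}. Two maps are provided: \code{"nandy"} walks the
#' sequence on a Cartesian lattice (residue classes nonpolar/polar/acidic/
#' basic step east/west/north/south; nodes are visited lattice points,
#' edges consecutive steps) and \code{"four_colour"} lays the sequence
#' row-wise into a near-square rectangle and connects grid neighbours of
#' the same class.
#'
#' @param seq sanitized amino-acid sequence.
#' @param map \code{"four_colour"} or \code{"nandy"}.
#' @param order number of spectral moments (default 15).
#' @return numeric vector \code{mu1..mu<order>}.
#' @export
graphicalMoments <- function(seq, map = c("four_colour", "nandy"),
                             order = 15L) {
  map <- match.arg(map)
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1", call. = FALSE)
  idx <- seqToInt(seq)
  n <- length(idx)
  cls <- .graphClass4(idx)
  if (map == "nandy") {
    steps <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
    xy <- apply(steps[cls, , drop = FALSE], 2L, cumsum)
    if (n == 1L) xy <- matrix(xy, nrow = 1L)
    key <- paste(xy[, 1], xy[, 2])
    node <- match(key, unique(key))
    nn <- max(node)
    A <- matrix(0, nn, nn)
    if (n > 1L) {
      from <- node[-n]; to <- node[-1]
      A[cbind(from, to)] <- 1
      A[cbind(to, from)] <- 1
    }
  } else {
    wdt <- ceiling(sqrt(n))
    row <- (seq_len(n) - 1L) %/% wdt
    col <- (seq_len(n) - 1L) %% wdt
    A <- matrix(0, n, n)
    right <- which(col < wdt - 1L & seq_len(n) + 1L <= n)
    right <- right[cls[right] == cls[right + 1L]]
    down <- which(seq_len(n) + wdt <= n)
    down <- down[cls[down] == cls[down + wdt]]
    if (length(right)) {
      A[cbind(right, right + 1L)] <- 1
      A[cbind(right + 1L, right)] <- 1
    }
    if (length(down)) {
      A[cbind(down, down + wdt)] <- 1
      A[cbind(down + wdt, down)] <- 1
    }
    nn <- n
  }
  rs <- rowSums(A)
  nz <- rs > 0
  A[nz, ] <- A[nz, , drop = FALSE] / rs[nz]
  mu <- numeric(order)
  P <- diag(nn)
  for (k in seq_len(order)) {
    P <- P %*% A
    mu[k] <- sum(diag(P)) / nn
  }
  names(mu) <- paste0("mu", seq_len(order))
  descriptorVector(mu, paste0("graphical_", map), list(order = order))
}
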