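# Independent brute-force oracles: every descriptor is recomputed here as
# literal formula loops over the sequence, sharing only the published
# per-residue tables with the package. Written before the optimized
# implementations and kept deliberately naive.

oracle_aac <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  vapply(AA20, function(a) sum(ch == a), numeric(1)) / length(ch)
}

oracle_pseaa <- function(seq, lam, w = 0.05) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  props <- scale(cbind(
    orthopair:::.KD_HYDROPHOBICITY,
    orthopair:::.HW_HYDROPHILICITY,
    orthopair:::.SIDE_CHAIN_MASS))
  rownames(props) <- AA20
  Theta <- function(a, b) mean((props[a, ] - props[b, ])^2)
  theta <- numeric(lam)
  for (j in seq_len(lam)) {
    acc <- 0
    for (i in seq_len(n - j)) acc <- acc + Theta(ch[i], ch[i + j])
    theta[j] <- acc / (n - j)
  }
  f <- vapply(AA20, function(a) sum(ch == a), numeric(1)) / n
  unname(c(f, w * theta) / (sum(f) + w * sum(theta)))
}

oracle_word <- function(seq, patterns) {
  ch <- strsplit(seq, "")[[1]]
  mp <- lapply(patterns, function(p) which(strsplit(p, "")[[1]] == "1"))
  k <- length(mp[[1]])
  words <- AA20
  if (k > 1) for (i in 2:k)
    words <- as.vector(t(outer(words, AA20, paste0)))
  counts <- setNames(numeric(length(words)), words)
  total <- 0
  for (m in mp) {
    L <- max(m)
    if (length(ch) < L) next
    for (s in 1:(length(ch) - L + 1)) {
      wd <- paste(ch[s + m - 1], collapse = "")
      counts[wd] <- counts[wd] + 1
      total <- total + 1
    }
  }
  if (total == 0) stop("zero windows")
  unname(counts / total)
}

oracle_autocorr <- function(seq, method, maxlag = 30) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  props <- aaPropertyTable(standardized = TRUE)
  one <- function(meth) {
    out <- numeric(0)
    for (a in colnames(props)) {
      p <- props[ch, a]
      pbar <- mean(p)
      ss <- sum((p - pbar)^2)
      for (d in 1:maxlag) {
        v <- 0
        if (ss > 0) {
          if (meth == "moreau_broto") {
            for (i in 1:(n - d)) v <- v + p[i] * p[i + d]
            v <- v / (n - d)
          } else if (meth == "moran") {
            num <- 0
            for (i in 1:(n - d)) num <- num + (p[i] - pbar) * (p[i + d] - pbar)
            v <- (num / (n - d)) / (ss / n)
          } else {
            num <- 0
            for (i in 1:(n - d)) num <- num + (p[i] - p[i + d])^2
            v <- (num / (2 * (n - d))) / (ss / (n - 1))
          }
        }
        out <- c(out, unname(v))
      }
    }
    out
  }
  if (method == "total") {
    v <- c(one("moreau_broto"), one("moran"), one("geary"))
    if (max(abs(v)) > 0) v <- v / max(abs(v))
    v
  } else one(method)
}

oracle_ctd <- function(seq, part) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  classes <- orthopair:::.CTD_CLASSES
  enc <- function(attr) {
    cls <- integer(n)
    for (k in 1:3) cls[ch %in% strsplit(classes[[attr]][k], "")[[1]]] <- k
    cls
  }
  C <- Tr <- D <- numeric(0)
  for (attr in names(classes)) {
    cls <- enc(attr)
    for (k in 1:3) C <- c(C, sum(cls == k) / n)
    pairs <- paste0(pmin(cls[-n], cls[-1]), pmax(cls[-n], cls[-1]))
    Tr <- c(Tr, sum(pairs == "12") / (n - 1), sum(pairs == "13") / (n - 1),
            sum(pairs == "23") / (n - 1))
    for (k in 1:3) {
      pos <- which(cls == k)
      if (!length(pos)) D <- c(D, rep(0, 5))
      else {
        m <- length(pos)
        D <- c(D, pos[1] / n, pos[ceiling(0.25 * m)] / n,
               pos[ceiling(0.5 * m)] / n, pos[ceiling(0.75 * m)] / n,
               pos[m] / n)
      }
    }
  }
  switch(part, C = C, T = Tr, D = D, total = c(C, Tr, D))
}

oracle_qso <- function(seq, maxlag = 30, w = 0.1,
                       dist = "schneider_wrede") {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  D <- aaDistanceMatrix(dist)
  tau <- numeric(maxlag)
  for (d in 1:maxlag) {
    for (i in 1:(n - d)) tau[d] <- tau[d] + D[ch[i], ch[i + d]]^2
  }
  f <- vapply(AA20, function(a) sum(ch == a), numeric(1)) / n
  unname(c(f, w * tau) / (sum(f) + w * sum(tau)))
}

oracle_moments <- function(seq, map, order = 15) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  grp <- c(A = 1, V = 1, L = 1, I = 1, P = 1, F = 1, M = 1, W = 1, G = 1,
           S = 2, T = 2, C = 2, Y = 2, N = 2, Q = 2,
           D = 3, E = 3, K = 4, R = 4, H = 4)
  cls <- unname(grp[ch])
  if (map == "nandy") {
    step <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    pos <- matrix(0, n, 2)
    cur <- c(0, 0)
    for (i in 1:n) {
      cur <- cur + step[[cls[i]]]
      pos[i, ] <- cur
    }
    key <- paste(pos[, 1], pos[, 2])
    nodes <- unique(key)
    A <- matrix(0, length(nodes), length(nodes))
    if (n > 1) for (i in 1:(n - 1)) {
      u <- match(key[i], nodes); v <- match(key[i + 1], nodes)
      A[u, v] <- 1; A[v, u] <- 1
    }
  } else {
    wdt <- ceiling(sqrt(n))
    A <- matrix(0, n, n)
    for (i in 1:n) {
      r <- (i - 1) %/% wdt; cc <- (i - 1) %% wdt
      for (j in 1:n) {
        r2 <- (j - 1) %/% wdt; c2 <- (j - 1) %% wdt
        if (abs(r - r2) + abs(cc - c2) == 1 && cls[i] == cls[j]) {
          A[i, j] <- 1; A[j, i] <- 1
        }
      }
    }
  }
  for (i in seq_len(nrow(A))) if (sum(A[i, ]) > 0) A[i, ] <- A[i, ] / sum(A[i, ])
  mu <- numeric(order)
  for (k in 1:order) {
    P <- diag(nrow(A))
    for (kk in 1:k) P <- P %*% A
    mu[k] <- sum(diag(P)) / nrow(A)
  }
  mu
}

# every family's oracle, keyed by the feature-column naming
oracle_families <- list(
  aac = function(s) oracle_aac(s),
  pseaa3 = function(s) oracle_pseaa(s, 3),
  pseaa4 = function(s) oracle_pseaa(s, 4),
  pseaa10 = function(s) oracle_pseaa(s, 10),
  `2-mers` = function(s) oracle_word(s, "11"),
  `2-mers_dc1` = function(s) oracle_word(s, "101"),
  `2-mers_dc2` = function(s) oracle_word(s, "1001"),
  `2-mers_dc3` = function(s) oracle_word(s, "10001"),
  `3-mers` = function(s) oracle_word(s, "111"),
  `3-mers_dc1` = function(s) oracle_word(s, c("1101", "1011")),
  `3-mers_dc2` = function(s) oracle_word(s, c("10011", "10101", "11001")),
  `3-mers_dc3` = function(s)
    oracle_word(s, c("100011", "110001", "101001", "100101")),
  Auto_Geary = function(s) oracle_autocorr(s, "geary"),
  Auto_Moran = function(s) oracle_autocorr(s, "moran"),
  Auto_Total = function(s) oracle_autocorr(s, "total"),
  CTD = function(s) oracle_ctd(s, "total"),
  CTD_C = function(s) oracle_ctd(s, "C"),
  CTD_T = function(s) oracle_ctd(s, "T"),
  CTD_D = function(s) oracle_ctd(s, "D"),
  fcm = function(s) oracle_moments(s, "four_colour"),
  nandy = function(s) oracle_moments(s, "nandy"),
  QSO_w01_maxlag30 = function(s) oracle_qso(s, dist = "schneider_wrede"),
  QSOCN_maxlag30 = function(s) oracle_qso(s, dist = "grantham"))

# the package-side counterparts of the oracles above
impl_families <- list(
  aac = function(s) aaComposition(s),
  pseaa3 = function(s) pseudoAAComposition(s, 3),
  pseaa4 = function(s) pseudoAAComposition(s, 4),
  pseaa10 = function(s) pseudoAAComposition(s, 10),
  `2-mers` = function(s) wordFrequencies(s, k = 2),
  `2-mers_dc1` = function(s) wordFrequencies(s, pattern = "101"),
  `2-mers_dc2` = function(s) wordFrequencies(s, pattern = "1001"),
  `2-mers_dc3` = function(s) wordFrequencies(s, pattern = "10001"),
  `3-mers` = function(s) wordFrequencies(s, k = 3),
  `3-mers_dc1` = function(s)
    wordFrequencies(s, pattern = c("1101", "1011")),
  `3-mers_dc2` = function(s)
    wordFrequencies(s, pattern = c("10011", "10101", "11001")),
  `3-mers_dc3` = function(s)
    wordFrequencies(s, pattern = c("100011", "110001", "101001",
                                   "100101")),
  Auto_Geary = function(s) aaAutocorrelation(s, "geary"),
  Auto_Moran = function(s) aaAutocorrelation(s, "moran"),
  Auto_Total = function(s) aaAutocorrelation(s, "total"),
  CTD = function(s) ctdDescriptor(s, "total"),
  CTD_C = function(s) ctdDescriptor(s, "C"),
  CTD_T = function(s) ctdDescriptor(s, "T"),
  CTD_D = function(s) ctdDescriptor(s, "D"),
  fcm = function(s) graphicalMoments(s, "four_colour"),
  nandy = function(s) graphicalMoments(s, "nandy"),
  QSO_w01_maxlag30 = function(s) qsoDescriptor(s, dist = "schneider_wrede"),
  QSOCN_maxlag30 = function(s) qsoDescriptor(s, dist = "grantham"))

# Pearson significance oracle via stats::cor.test
oracle_gate <- function(vx, vy, alpha = 0.05) {
  if (sd(vx) == 0 || sd(vy) == 0) return(0)
  ct <- suppressWarnings(cor.test(vx, vy))
  if (!is.na(ct$p.value) && ct$p.value <= alpha) unname(ct$estimate) else 0
}
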