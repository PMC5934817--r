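test_that("gated Pearson similarity returns r only when significant", {
  set.seed(31)
  v <- rnorm(10)
  expect_equal(pearsonGatedSimilarity(v, v), 1)
  expect_equal(pearsonGatedSimilarity(v, -v), -1)
  expect_equal(pearsonGatedSimilarity(rep(1, 5), rnorm(5)), 0)
  expect_error(pearsonGatedSimilarity(rnorm(5), rnorm(6)), "dimension")
  expect_error(pearsonGatedSimilarity(rnorm(2), rnorm(2)), ">= 3")
  expect_error(
    pearsonGatedSimilarity(aaComposition("MKV"),
                           pseudoAAComposition("MKV", 0)),
    "famil")
  expect_error(
    pearsonGatedSimilarity(pseudoAAComposition("MKVLAW", 2),
                           pseudoAAComposition("MKVLAW", 2, w = 0.1)),
    "parameters")
  # weakly correlated short vectors fail the gate
  for (i in 1:200) {
    vx <- rnorm(4); vy <- rnorm(4)
    expect_equal(pearsonGatedSimilarity(vx, vy), oracle_gate(vx, vy),
                 tolerance = 1e-12)
  }
})

test_that("max-normalization preserves sign and all-zero columns", {
  expect_equal(normalizeByMax(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalizeByMax(c(0, 0)), c(0, 0))
  expect_equal(normalizeByMax(c(-1, 2)), c(-0.5, 1))
  expect_error(normalizeByMax(c(1, NA)), "finite")
})

test_that("feature sets partition into 5 + 24 = 29 named columns", {
  expect_length(featureColumnNames("combined"), 29)
  expect_length(featureColumnNames("ab"), 5)
  expect_length(featureColumnNames("af"), 24)
  expect_setequal(featureColumnNames("combined"),
                  c(featureColumnNames("ab"), featureColumnNames("af")))
  toy <- toyProteomes()
  for (s in c("combined", "ab", "af")) {
    pf <- buildFeatureMatrix(toy$p1, toy$p2, set = s)
    expect_identical(colnames(featureMatrix(pf)), featureColumnNames(s))
  }
})

test_that("feature matrices are byte-identical across runs", {
  toy <- toyProteomes()
  f1 <- tempfile(); f2 <- tempfile()
  writeFeatureTable(buildFeatureMatrix(toy$p1, toy$p2), f1)
  writeFeatureTable(buildFeatureMatrix(toy$p1, toy$p2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the built matrix equals a straight-line per-pair oracle", {
  toy <- toyProteomes()
  pf <- buildFeatureMatrix(toy$p1, toy$p2)
  got <- featureMatrix(pf)
  pairs <- enumeratePairs(toy$p1, toy$p2)
  s1 <- as.character(toy$p1); s2 <- as.character(toy$p2)
  raw <- matrix(0, nrow(pairs), 29,
                dimnames = list(NULL, featureColumnNames()))
  for (i in seq_len(nrow(pairs))) {
    x <- s1[[pairs$id1[i]]]; y <- s2[[pairs$id2[i]]]
    g <- alignPair(x, y, "global")
    l <- alignPair(x, y, "local")
    raw[i, "nw"] <- g@score
    raw[i, "sw"] <- l@score
    raw[i, "profile3"] <- profileSimilarity(g, 3)
    raw[i, "profile5"] <- profileSimilarity(g, 5)
    raw[i, "profile7"] <- profileSimilarity(g, 7)
    raw[i, "length"] <- lengthSimilarity(x, y)
    for (fam in names(oracle_families))
      raw[i, fam] <- oracle_gate(oracle_families[[fam]](x),
                                 oracle_families[[fam]](y))
  }
  expected <- apply(raw, 2, function(col)
    if (max(abs(col)) == 0) col else col / max(abs(col)))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("undefined descriptors become zero similarities, not NAs", {
  p1 <- Biostrings::AAStringSet(c(long1 = strrep("MKVLAWGKHQ", 4),
                                  short = "MKVLAWGK"))
  p2 <- Biostrings::AAStringSet(c(long2 = strrep("MKVLPWGKHQ", 4)))
  expect_message(
    pf <- buildFeatureMatrix(p1, p2, set = "af", verbose = TRUE),
    "undefined")
  m <- featureMatrix(pf)
  expect_false(anyNA(m))
  short_row <- which(pairIds(pf)$id1 == "short")
  for (col in c("Auto_Geary", "QSO_w01_maxlag30", "pseaa10"))
    expect_equal(unname(m[short_row, col]), 0)
  # the defined pair keeps nonzero similarity on composition
  expect_gt(abs(m[1, "aac"]), 0)
})

test_that("normalization makes every nonzero column peak at 1", {
  toy <- toyProteomes()
  m <- featureMatrix(buildFeatureMatrix(toy$p1, toy$p2))
  for (j in seq_len(ncol(m))) {
    mx <- max(abs(m[, j]))
    expect_true(mx == 0 || abs(mx - 1) < 1e-12)
  }
  # a single-pair matrix: every column is 1 or 0 by construction
  one <- buildFeatureMatrix(toy$p1[1], toy$p2[1])
  expect_true(all(featureMatrix(one) %in% c(0, 1) |
                  abs(abs(featureMatrix(one)) - 1) < 1e-12))
  expect_equal(unname(featureMatrix(one)[1, c("nw", "sw")]), c(1, 1))
})
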