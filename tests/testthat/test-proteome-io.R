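test_that("FASTA proteomes are read in order with sanitized residues", {
  f <- writeFasta(list(a = "MKV", b = "GG"))
  p <- readProteome(f)
  expect_identical(names(p), c("a", "b"))
  expect_identical(unname(Biostrings::width(p)), c(3L, 2L))

  f2 <- writeFasta(list(c = "MKV*"))
  expect_identical(as.character(readProteome(f2)[["c"]]), "MKV")

  fdup <- writeFasta(list(a = "MK"))
  cat(">a\nGG\n", file = fdup, append = TRUE)
  expect_error(readProteome(fdup), "duplicate.*a")

  fempty <- tempfile()
  writeLines(c(">a", "", ">b", "MK"), fempty)
  expect_error(readProteome(fempty), "empty")
})

test_that("non-canonical residues follow the sanitization policy", {
  expect_identical(sanitizeSequence("MUKOV"), "MCKKV")
  expect_identical(sanitizeSequence("BZJ"), "DEL")
  # X resolves to the most frequent canonical residue of the sequence
  expect_identical(sanitizeSequence("AAGX"), "AAGA")
  expect_error(sanitizeSequence("XX"), "canonical")
  expect_error(sanitizeSequence("MKX", policy = "strict"),
               "strict")
  expect_identical(sanitizeSequence("MKV", policy = "strict"), "MKV")
})

test_that("gold labels imply the negative universe and validate ids", {
  set.seed(42)
  p1 <- Biostrings::AAStringSet(setNames(replicate(10, randomSeq(30)),
                                         paste0("x", 1:10)))
  p2 <- Biostrings::AAStringSet(setNames(replicate(10, randomSeq(30)),
                                         paste0("y", 1:10)))
  f <- tempfile()
  writeLines(c("x1\ty1", "x2\ty5", "x9\ty9"), f, sep = "\n")
  gold <- loadGoldLabels(f, p1, p2)
  expect_equal(nrow(orthologPairs(gold)), 3)
  lab <- labelPairs(gold, enumeratePairs(p1, p2))
  expect_equal(sum(lab == 1L), 3)
  expect_equal(sum(lab == 0L), 97)

  fe <- tempfile(); file.create(fe)
  gold0 <- loadGoldLabels(fe, p1, p2)
  expect_equal(nrow(orthologPairs(gold0)), 0)
  expect_equal(sum(labelPairs(gold0, enumeratePairs(p1, p2))), 0)

  fb <- tempfile()
  writeLines("x1\tzz", fb)
  expect_error(loadGoldLabels(fb, p1, p2), "zz")

  fd <- tempfile()
  writeLines(c("x1\ty1", "x1\ty1"), fd)
  expect_error(loadGoldLabels(fd, p1, p2), "duplicated")
})

test_that("pair enumeration is the lexicographic cross product", {
  mk <- function(n, pre) {
    v <- rep("MK", n)
    names(v) <- as.character(seq_len(n) + 0)  # length-0 safe
    if (n) names(v) <- paste0(pre, seq_len(n))
    v
  }
  pr <- enumeratePairs(mk(3, "a"), mk(4, "b"))
  expect_equal(nrow(pr), 12)
  expect_identical(pr$id1[1:4], rep("a1", 4))
  expect_identical(pr$id2[1:4], paste0("b", 1:4))
  expect_equal(nrow(enumeratePairs(mk(1, "a"), mk(1, "b"))), 1)
  expect_error(enumeratePairs(mk(0, "a"), mk(2, "b")), "non-empty")
  for (n1 in 1:50) for (n2 in 1:50)
    if (nrow(enumeratePairs(mk(n1, "a"), mk(n2, "b"))) != n1 * n2)
      fail(sprintf("count mismatch at %d x %d", n1, n2))
  succeed()
})

test_that("read -> write -> read is the identity on (id, seq)", {
  set.seed(7)
  seqs <- setNames(replicate(5, randomSeq(sample(20:60, 1))),
                   paste0("prot", 1:5))
  p <- readProteome(writeFasta(as.list(seqs)))
  f2 <- tempfile(fileext = ".fasta")
  writeProteome(p, f2)
  p2 <- readProteome(f2)
  expect_identical(names(p2), names(p))
  expect_identical(as.character(p2), as.character(p))
})

test_that("descriptors ignore FASTA line wrapping", {
  set.seed(11)
  s <- randomSeq(120)
  p_wide <- readProteome(writeFasta(list(p = s)))
  p_wrap <- readProteome(writeFasta(list(p = s), width = 17))
  expect_identical(as.character(p_wide), as.character(p_wrap))
  expect_equal(aaComposition(as.character(p_wrap[["p"]])),
               aaComposition(s))
})

test_that("feature tables round-trip through TSV", {
  toy <- toyProteomes()
  pf <- buildFeatureMatrix(toy$p1, toy$p2, set = "ab")
  pairLabels(pf) <- c(1L, rep(0L, 8))
  f <- tempfile(fileext = ".tsv")
  writeFeatureTable(pf, f)
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, c("id1", "id2", featureColumnNames("ab"), "label"))
  back <- readFeatureTable(f)
  expect_equal(featureMatrix(back), featureMatrix(pf), tolerance = 1e-12)
  expect_identical(pairLabels(back), pairLabels(pf))
})
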