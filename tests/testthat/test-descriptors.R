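test_that("amino acid composition is the residue fraction vector", {
  v <- aaComposition("AAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(aaComposition("ACAC")[c("A", "C")]), c(0.5, 0.5))
  expect_equal(as.numeric(aaComposition(paste(AA20, collapse = ""))),
               rep(0.05, 20))
  expect_error(aaComposition(""), "residues|empty")
})

test_that("pseudo amino acid composition honours the lambda contract", {
  s <- "MKVLAWGKHM"
  expect_equal(as.numeric(pseudoAAComposition(s, 0)),
               as.numeric(aaComposition(s)))
  expect_error(pseudoAAComposition("ACA", 4), "lambda")
  v <- pseudoAAComposition("MKVLAW", 2, w = 0.05)
  expect_length(v, 22)
  expect_equal(sum(v), 1)
  expect_equal(as.numeric(v), oracle_pseaa("MKVLAW", 2), tolerance = 1e-12)
})

test_that("word frequencies count through match/don't-care patterns", {
  v <- wordFrequencies("ACAC", k = 2)
  expect_equal(unname(v[c("AC", "CA")]), c(2 / 3, 1 / 3))
  v2 <- wordFrequencies("ACAC", pattern = "101")
  expect_equal(unname(v2[c("AA", "CC")]), c(0.5, 0.5))
  expect_equal(unname(wordFrequencies("AAA", k = 3)["AAA"]), 1)
  expect_error(wordFrequencies("AC", pattern = "101"), "zero windows")
  expect_error(wordFrequencies("ACAC", pattern = "010"), "start and end")
  # pooled patterns share one vector and one window total
  v3 <- wordFrequencies("ACACA", pattern = c("1101", "1011"))
  expect_equal(as.numeric(v3),
               oracle_word("ACACA", c("1101", "1011")), tolerance = 1e-12)
})

test_that("all-match patterns reduce to contiguous k-mers", {
  set.seed(5)
  for (s in replicate(5, randomSeq(50))) {
    expect_equal(as.numeric(wordFrequencies(s, pattern = "11")),
                 as.numeric(wordFrequencies(s, k = 2)))
    expect_equal(as.numeric(wordFrequencies(s, pattern = "111")),
                 as.numeric(wordFrequencies(s, k = 3)))
  }
})

test_that("autocorrelation matches closed forms and degenerate rules", {
  hom <- strrep("A", 40)
  for (m in c("geary", "moran", "moreau_broto", "total"))
    expect_true(all(aaAutocorrelation(hom, m, 5) == 0))
  # perfect alternation gives Moran I = -1 at lag 1 for every attribute
  # that separates the two residues
  alt <- paste(rep(c("A", "D"), 20), collapse = "")
  v <- aaAutocorrelation(alt, "moran", 1)
  expect_equal(unname(v["charge.lag1"]), -1, tolerance = 1e-12)
  expect_equal(unname(v["hydrophobicity.lag1"]), -1, tolerance = 1e-12)
  # brute-force check at a single lag
  s <- "ACACACACACAC"
  v2 <- aaAutocorrelation(s, "moreau_broto", 2)
  expect_equal(as.numeric(v2), oracle_autocorr(s, "moreau_broto", 2),
               tolerance = 1e-12)
  expect_error(aaAutocorrelation("MKV", "moran", 10), "maxlag")
})

test_that("CTD parts follow their definitions", {
  hom <- strrep("A", 15)
  vc <- ctdDescriptor(hom, "C")
  # each attribute's triple has a single 1 at A's class
  m <- matrix(vc, nrow = 3)
  expect_true(all(colSums(m) == 1))
  expect_true(all(colSums(m == 1) == 1))
  expect_true(all(ctdDescriptor(hom, "T") == 0))
  # A and R are in different hydrophobicity classes: single transition
  vt <- ctdDescriptor("AR", "T")
  expect_equal(unname(vt["hydrophobicity.T12"]), 1)
  expect_length(ctdDescriptor(hom, "total"), 147)
  expect_length(ctdDescriptor(hom, "D"), 105)
  expect_error(ctdDescriptor("A", "T"), "2 residues")
})

test_that("quasi-sequence-order reduces to composition on homopolymers", {
  hom <- strrep("A", 40)
  v <- qsoDescriptor(hom, 30)
  expect_equal(unname(v["A"]), 1)
  expect_true(all(v[21:50] == 0))
  set.seed(3)
  s <- randomSeq(35)
  expect_equal(sum(qsoDescriptor(s, 3)), 1)
  expect_equal(as.numeric(qsoDescriptor(s, 3)),
               oracle_qso(s, 3), tolerance = 1e-12)
  expect_error(qsoDescriptor(s, 40), "maxlag")
})

test_that("graphical moments follow the map constructions", {
  expect_true(all(graphicalMoments("M", "nandy") == 0))
  expect_true(all(graphicalMoments("M", "four_colour") == 0))
  # A (east) then D (north) visits two lattice points joined by one edge:
  # the 2-node cycle has mu_k = 0 (odd k), 1 (even k)
  v <- graphicalMoments("AD", "nandy", 6)
  expect_equal(as.numeric(v), rep(c(0, 1), 3))
  set.seed(9)
  s <- randomSeq(30)
  expect_equal(as.numeric(graphicalMoments(s, "nandy")),
               oracle_moments(s, "nandy"), tolerance = 1e-10)
  expect_equal(as.numeric(graphicalMoments(s, "four_colour")),
               oracle_moments(s, "four_colour"), tolerance = 1e-10)
})

test_that("descriptor dimensions depend only on family and parameters", {
  set.seed(21)
  seqs <- replicate(30, randomSeq(sample(35:90, 1)))
  for (fam in names(impl_families)) {
    dims <- vapply(seqs, function(s) length(impl_families[[fam]](s)),
                   integer(1))
    expect_length(unique(dims), 1)
  }
})

test_that("composition-like descriptors are non-negative and sum to 1", {
  set.seed(22)
  for (s in replicate(10, randomSeq(sample(35:80, 1)))) {
    for (v in list(aaComposition(s), pseudoAAComposition(s, 5),
                   qsoDescriptor(s, 30), qsoDescriptor(s, 30,
                                                       dist = "grantham"))) {
      expect_true(all(v >= 0))
      expect_equal(sum(v), 1, tolerance = 1e-12)
    }
  }
})
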