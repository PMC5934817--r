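mkData <- function(nNeg, nPos, p = 3) {
  list(matrix = matrix(seq_len((nNeg + nPos) * p), ncol = p,
                       dimnames = list(NULL, paste0("f", 1:p))),
       labels = rep(c(0L, 1L), c(nNeg, nPos)))
}

test_that("random oversampling grows the minority to sizePct of majority", {
  d <- mkData(1000, 10)
  r100 <- randomOversample(d$matrix, d$labels, 100, seed = 1)
  expect_equal(as.vector(table(r100$labels)), c(1000, 1000))
  r130 <- randomOversample(d$matrix, d$labels, 130, seed = 1)
  expect_equal(as.vector(table(r130$labels)), c(1000, 1300))
  b <- mkData(5, 5)
  rb <- randomOversample(b$matrix, b$labels, 100, seed = 1)
  expect_equal(as.vector(table(rb$labels)), c(5, 5))
  expect_error(randomOversample(d$matrix, rep(0L, 1010), 100, 1),
               "both classes")
  # never drops a row: originals are a sub-multiset of the output
  orig_keys <- apply(d$matrix, 1, paste, collapse = ",")
  out_keys <- apply(r130$matrix, 1, paste, collapse = ",")
  expect_true(all(orig_keys %in% out_keys))
  expect_true(all(out_keys %in% orig_keys))
})

test_that("random undersampling balances without duplicating rows", {
  d <- mkData(1000, 10)
  r <- randomUndersample(d$matrix, d$labels, seed = 3)
  expect_equal(as.vector(table(r$labels)), c(10, 10))
  keys <- apply(r$matrix, 1, paste, collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  b <- mkData(7, 7)
  expect_equal(as.vector(table(randomUndersample(b$matrix, b$labels, 1)$labels)),
               c(7, 7))
  r2 <- randomUndersample(d$matrix, d$labels, seed = 3)
  expect_identical(r$matrix, r2$matrix)
})

test_that("resampling count postconditions hold over random configs", {
  set.seed(41)
  for (i in 1:30) {
    nNeg <- sample(20:300, 1); nPos <- sample(2:19, 1)
    pct <- sample(c(50, 100, 130, 200), 1)
    d <- mkData(nNeg, nPos)
    ro <- randomOversample(d$matrix, d$labels, pct, seed = i)
    expect_equal(sum(ro$labels == 1L), max(nPos, round(pct / 100 * nNeg)))
    expect_equal(sum(ro$labels == 0L), nNeg)
    ru <- randomUndersample(d$matrix, d$labels, seed = i)
    expect_equal(as.vector(table(ru$labels)), c(nPos, nPos))
  }
})

separableData <- function(n = 120, seed = 51) {
  withr::with_seed(seed, {
    lab <- rep(c(0L, 1L), c(n - 20, 20))
    m <- cbind(sw = lab + rnorm(n, sd = 0.05),
               nw = rnorm(n), `2-mers` = rnorm(n))
    list(matrix = m, labels = lab)
  })
}

test_that("training honours the resampling and determinism contracts", {
  d <- separableData()
  m <- trainOrthologModel(d$matrix, d$labels, "decision_tree",
                          resampling = resamplingSpec("RUS", seed = 2))
  pr <- predictOrthologs(m, d$matrix)
  expect_identical(pr, d$labels)
  expect_equal(unname(m@classCounts$after), c(20, 20))
  expect_equal(unname(m@classCounts$before), c(100, 20))

  m2 <- trainOrthologModel(d$matrix, d$labels, "random_forest",
                           resampling = resamplingSpec("ROS", 130, seed = 2),
                           seed = 9)
  m3 <- trainOrthologModel(d$matrix, d$labels, "random_forest",
                           resampling = resamplingSpec("ROS", 130, seed = 2),
                           seed = 9)
  test <- separableData(seed = 99)
  expect_identical(predictOrthologs(m2, test$matrix),
                   predictOrthologs(m3, test$matrix))
  expect_equal(unname(m2@classCounts$after), c(100, 130))

  expect_error(trainOrthologModel(d$matrix, rep(1L, nrow(d$matrix)),
                                  "decision_tree"), "both classes")
  expect_error(trainOrthologModel(d$matrix, d$labels, "boosting"),
               "arg")
})

test_that("prediction enforces the training feature order", {
  d <- separableData()
  m <- trainOrthologModel(d$matrix, d$labels, "decision_tree")
  expect_identical(predictOrthologs(m, d$matrix[0, , drop = FALSE]),
                   integer(0))
  shuffled <- d$matrix[, c(2, 1, 3)]
  expect_error(predictOrthologs(m, shuffled), "nw")
  renamed <- d$matrix
  colnames(renamed)[2] <- "bogus"
  expect_error(predictOrthologs(m, renamed), "bogus")
})

test_that("impurity importance concentrates on the informative feature", {
  d <- separableData(n = 300)
  for (algo in c("random_forest", "decision_tree")) {
    m <- trainOrthologModel(d$matrix, d$labels, algo)
    imp <- featureImportance(m)
    expect_named(imp, colnames(d$matrix))
    expect_true(all(imp >= 0))
    expect_equal(sum(imp), 1)
    expect_gt(imp[["sw"]], 0.8)
  }
  ml <- suppressWarnings(trainOrthologModel(d$matrix, d$labels, "logreg"))
  expect_error(featureImportance(ml), "tree-based")
})

test_that("no-signal features share a uniform noise-floor importance", {
  withr::with_seed(77, {
    m <- cbind(a = rnorm(400), b = rnorm(400), c = rnorm(400))
    lab <- rep(c(0L, 1L), 200)
  })
  fit <- trainOrthologModel(m, lab, "random_forest")
  imp <- featureImportance(fit)
  expect_equal(sum(imp), 1)
  expect_true(all(imp < 0.6))  # nothing dominates without signal
})
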