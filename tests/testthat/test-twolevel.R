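test_that("a separable problem is fit perfectly and bad configs rejected", {
  d <- separableClusters(15, seed = 1)
  fit <- trainLevel(d$x, d$y, gamma = 0.5, cost = 10)
  expect_equal(as.character(predict(fit, d$x)), d$y)
  expect_error(trainLevel(d$x, d$y, gamma = 0, cost = 10), "gamma")
  expect_error(trainLevel(d$x, d$y, gamma = -1, cost = 10), "gamma")
  expect_error(trainLevel(d$x, d$y, gamma = 0.5, cost = 0), "cost")
  expect_error(trainLevel(d$x, rep("1", 30), gamma = 0.5, cost = 10),
               "two classes")
  expect_error(trainLevel(d$x, d$y[-1], gamma = 0.5, cost = 10),
               "parallel")
})

test_that("duplicating every training point leaves its labels unchanged", {
  d <- separableClusters(12, seed = 2)
  fit1 <- trainLevel(d$x, d$y, gamma = 0.5, cost = 10)
  dup <- rbind(d$x, d$x)
  rownames(dup) <- sprintf("d%02d", seq_len(nrow(dup)))
  fit2 <- trainLevel(dup, c(d$y, d$y), gamma = 0.5, cost = 10)
  expect_equal(as.character(predict(fit2, d$x)),
               as.character(predict(fit1, d$x)))
})

test_that("grid search is exhaustive, deterministic, and tie-broken", {
  d <- separableClusters(10, seed = 3)
  single <- gridSearch(d$x, d$y, gammaGrid = 0.7, costGrid = 3, k = 3)
  expect_equal(single$gamma, 0.7)
  expect_equal(single$cost, 3)
  expect_equal(nrow(single$table), 1L)

  gs <- gridSearch(d$x, d$y, gammaGrid = c(0.1, 0.5, 2),
                   costGrid = c(1, 10), k = 3, seed = 5)
  # argmax: the winner is at least as good as any other grid point
  expect_true(all(gs$table$accuracy <=
    gs$table$accuracy[gs$table$gamma == gs$gamma & gs$table$cost == gs$cost]))
  # ties break towards smaller cost, then smaller gamma
  best <- gs$table[gs$table$accuracy == max(gs$table$accuracy), ]
  best <- best[order(best$cost, best$gamma), ][1, ]
  expect_equal(c(gs$gamma, gs$cost), c(best$gamma, best$cost))
  gs2 <- gridSearch(d$x, d$y, gammaGrid = c(0.1, 0.5, 2),
                    costGrid = c(1, 10), k = 3, seed = 5)
  expect_equal(gs$table, gs2$table)
  expect_error(gridSearch(d$x, d$y, numeric(0), 1), "non-empty")
  expect_error(gridSearch(d$x, d$y, 1, 1, k = 1), "at least 2")
})

test_that("the cascade gates level 2 behind level 1 and recovers planted classes", {
  x <- smallCascadeCollection(seed = 11)
  model <- trainTwoLevel(x, featureSet = "AAC+CTF",
                         level1Params = c(gamma = 8, cost = 10),
                         level2Params = c(gamma = 8, cost = 10))
  pred <- predictTwoLevel(model, x)
  expect_setequal(levels(pred), c("non-NR", "NR1", "NR3"))

  # cascade consistency: level-1 negatives are exactly the non-NR outputs
  m <- featureValues(computeFeatures(x, "AAC+CTF"))
  l1 <- as.character(predict(model@level1, m))
  expect_equal(unname(pred == "non-NR"), l1 == "0")

  # planted subfamily biases are recovered on the training collection
  truth <- as.character(classLabels(x))
  expect_gte(mean(as.character(pred) == truth), 0.95)

  # a fresh NR3-biased record routes through level 2 to NR3
  fresh <- generateCollection(c(NR3 = 4L), lengthRange = c(60L, 120L),
                              motifs = list(NR3 = c("C-RK-AGV",
                                                    "HNQW-HNQW-HNQW")),
                              weights = list(NR3 = c(4, 5)), seed = 99)
  predFresh <- predictTwoLevel(model, sequences(fresh))
  expect_true(all(predFresh == "NR3"))
})

test_that("models survive a save/load round trip with identical predictions", {
  x <- smallCascadeCollection(seed = 12)
  model <- trainTwoLevel(x, featureSet = "AAC+CTF",
                         level1Params = c(gamma = 8, cost = 10),
                         level2Params = c(gamma = 8, cost = 10))
  holdout <- sequences(generateCollection(
    c(NR1 = 3L, "non-NR" = 3L), lengthRange = c(60L, 100L),
    motifs = list(NR1 = c("C-RK-AGV", "ILFP-ILFP-ILFP")),
    weights = list(NR1 = c(4, 5)), seed = 77))
  p1 <- predictTwoLevel(model, holdout)
  path <- tempfile(fileext = ".rds")
  saveTwoLevelModel(model, path)
  restored <- readTwoLevelModel(path)
  expect_identical(predictTwoLevel(restored, holdout), p1)
  # inference is deterministic
  expect_identical(predictTwoLevel(model, holdout), p1)
})

test_that("feature-set mismatches between model and input are rejected", {
  x <- smallCascadeCollection(seed = 13)
  model <- trainTwoLevel(x, featureSet = "CTF",
                         level1Params = c(gamma = 0.5, cost = 10),
                         level2Params = c(gamma = 8, cost = 10))
  aac <- computeAAC(sequences(x))
  expect_error(predictTwoLevel(model, aac), "mismatch")
  bogus <- tempfile(fileext = ".rds")
  saveRDS(list(), bogus)
  expect_error(readTwoLevelModel(bogus), "TwoLevelModel")
})
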