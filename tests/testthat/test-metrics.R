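test_that("binary metrics follow the confusion-count formulas", {
  perfect <- reportMetrics(binaryMetrics(TP = 50, FN = 0, TN = 50, FP = 0))
  expect_equal(unname(perfect[c("sens", "spec", "acc", "mcc")]),
               c(1, 1, 1, 1))

  chance <- reportMetrics(binaryMetrics(TP = 25, FP = 25, TN = 25, FN = 25))
  expect_equal(unname(chance["mcc"]), 0)
  expect_equal(unname(chance["acc"]), 0.5)

  # 447 of 474 positives recovered
  sens <- reportMetrics(binaryMetrics(TP = 447, FN = 27, TN = 1, FP = 1))["sens"]
  expect_equal(round(unname(sens), 4), 0.9430)

  # zero factor under the square root -> MCC = 0 by convention
  degen <- reportMetrics(binaryMetrics(TP = 10, FN = 0, TN = 0, FP = 5))
  expect_equal(unname(degen["mcc"]), 0)

  expect_error(binaryMetrics(TP = 0, FP = 0, TN = 0, FN = 0), "total")
})

test_that("confusion counts tally as defined", {
  cc <- confusionCounts(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(cc, c(TP = 2L, FP = 1L, TN = 1L, FN = 1L))
})

test_that("per-class metrics reproduce the one-vs-rest counting scheme", {
  # a subfamily of 162 with 4 members misassigned
  truth <- c(rep("NR1", 162), rep("NR2", 50))
  pred <- truth
  pred[1:4] <- "NR2"
  rep1 <- perClassMetrics(truth, pred)
  pc <- perClassTable(rep1)
  expect_equal(round(pc$sens[pc$class == "NR1"], 4), 0.9753)
  expect_equal(pc$TP[pc$class == "NR1"], 158)

  # all correct -> everything 1
  allok <- perClassMetrics(truth, truth)
  expect_true(all(perClassTable(allok)[, c("sens", "spec", "acc", "mcc")] == 1))
  expect_equal(unname(reportMetrics(allok)[c("sens", "mcc")]), c(1, 1))

  expect_error(perClassMetrics(c("NR1", "NR9"), c("NR1", "NR1"),
                               classes = c("NR1", "NR2")), "NR9")
})

test_that("a 3-class toy matches a hand-enumerated count oracle", {
  # classes of sizes 4, 3, 3; one cross-error each way between A and B
  truth <- c("A", "A", "A", "A", "B", "B", "B", "C", "C", "C")
  pred  <- c("A", "A", "A", "B", "A", "B", "B", "C", "C", "C")
  rep3 <- perClassMetrics(truth, pred, classes = c("A", "B", "C"))
  pc <- perClassTable(rep3)
  # hand enumeration: A: N+=4, missed out 1, missed in 1 -> TP=3 TN=5 FP=1 FN=1
  expect_equal(unlist(pc[pc$class == "A", c("TP", "TN", "FP", "FN")]),
               c(TP = 3, TN = 5, FP = 1, FN = 1))
  expect_equal(pc$sens[1], 3 / 4)
  expect_equal(pc$spec[1], 5 / 6)
  expect_equal(pc$acc[1], 8 / 10)
  expect_equal(pc$mcc[1],
               (3 * 5 - 1 * 1) / sqrt((3 + 1) * (3 + 1) * (5 + 1) * (5 + 1)))
  # B mirrors A; C is perfect
  expect_equal(unlist(pc[pc$class == "C", c("TP", "TN", "FP", "FN")]),
               c(TP = 3, TN = 7, FP = 0, FN = 0))
  # overall sensitivity is the pooled correct rate 8/10
  expect_equal(unname(reportMetrics(rep3)["sens"]), 0.8)
})

test_that("metrics from label lists equal independently tallied counts", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    truth <- sample(c("0", "1"), n, TRUE)
    pred <- sample(c("0", "1"), n, TRUE)
    if (length(unique(truth)) < 2) next
    # independent tally
    TP <- sum(truth == "1" & pred == "1")
    FP <- sum(truth == "0" & pred == "1")
    TN <- sum(truth == "0" & pred == "0")
    FN <- sum(truth == "1" & pred == "0")
    got <- reportMetrics(binaryMetrics(confusionCounts(truth, pred)))
    expect_equal(unname(got["acc"]), (TP + TN) / n)
    if (TP + FN > 0) expect_equal(unname(got["sens"]), TP / (TP + FN))
    if (TN + FP > 0) expect_equal(unname(got["spec"]), TN / (TN + FP))
  }
})

test_that("AUC equals the pairwise Mann-Whitney probability", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_equal(rocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")

  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    labels <- c("1", "0", sample(c("0", "1"), n - 2, TRUE))
    scores <- round(rnorm(n), 1)  # rounding forces ties
    expect_equal(rocAuc(scores, labels)$auc, aucOracle(scores, labels))
  }
})

test_that("ROC curves run from (0,0) to (1,1) and agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- rnorm(40)
  labels <- sample(c("0", "1"), 40, TRUE)
  got <- rocAuc(scores, labels)
  expect_equal(got$curve$fpr[1], 0)
  expect_equal(got$curve$tpr[1], 0)
  expect_equal(got$curve$fpr[nrow(got$curve)], 1)
  expect_equal(got$curve$tpr[nrow(got$curve)], 1)
  ref <- pROC::auc(pROC::roc(labels, scores, levels = c("0", "1"),
                             direction = "<", quiet = TRUE))
  expect_equal(got$auc, as.numeric(ref))
})

test_that("metrics reports serialize to TSV and JSON", {
  rep1 <- binaryMetrics(TP = 40, FP = 5, TN = 45, FN = 10, auc = 0.9)
  tsv <- tempfile(fileext = ".tsv")
  writeMetricsReport(rep1, tsv)
  expect_equal(strsplit(readLines(tsv)[1], "\t")[[1]],
               c("sens", "spec", "acc", "mcc", "auc"))
  js <- tempfile(fileext = ".json")
  writeMetricsReport(rep1, js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$metrics$acc, 0.85)
})
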