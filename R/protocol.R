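## The full benchmark protocol: evaluate all (or selected) feature sets
## at both cascade levels by cross-validation, producing the standard
## three-part report (binary comparison table, subfamily comparison
## table, per-subfamily detail).

#' Run the feature-set comparison protocol
#'
#' For every requested feature set, encodes the collection once, then
#' (1) cross-validates the binary NR / non-NR level on all samples,
#' reporting fold-averaged Sens/Spec/Acc/MCC/AUC, and (2)
#' cross-validates the subfamily level on the NR samples only,
#' reporting pooled overall sensitivity and MCC plus the per-subfamily
#' detail table.  `test = "jackknife"` switches both levels to
#' leave-one-out (deterministic, seed-free).
#'
#' @param x An [Biostrings::AAStringSet] of validated sequences or a
#'   [LabeledProteinSet-class].
#' @param labels Parallel labels (`"non-NR"`/`"0"` for negatives,
#'   subfamily labels for positives); defaults to the collection's
#'   labels.
#' @param featureSets Character vector of feature sets to evaluate
#'   (default: all seven).
#' @param k Folds for `test = "kfold"` (default 10).
#' @param seed Seed for the fold shuffle.
#' @param test `"kfold"` (default) or `"jackknife"`.
#' @param cgrAlpha Twelve-group vertex alphabet for CGR encoding.
#' @return List of class `"nrProtocolReport"` with elements `level1`
#'   (data frame: one row per feature set with dimension and binary
#'   metrics), `level2` (data frame: overall subfamily metrics and the
#'   `(gamma, cost)` used), `perClass` (named list of per-subfamily
#'   detail tables), `test`, `k`, `seed`.
#' @export
runFeatureSetComparison <- function(x, labels = NULL,
                                    featureSets = featureSetNames(),
                                    k = 10L, seed = 1L,
                                    test = c("kfold", "jackknife"),
                                    cgrAlpha = cgrAlphabet()) {
  test <- match.arg(test)
  if (is(x, "LabeledProteinSet")) {
    if (is.null(labels)) labels <- classLabels(x)
    x <- sequences(x)
  }
  labels <- as.character(labels)
  stopifnot(length(x) == length(labels))
  negative <- labels %in% c("non-NR", "0")
  binary <- ifelse(negative, "0", "1")
  sub <- labels[!negative]
  level1 <- NULL; level2 <- NULL; perClass <- list()
  for (fs in featureSets) {
    fs <- normalizeFeatureSet(fs)
    feats <- computeFeatures(x, fs, cgrAlpha = cgrAlpha)
    p1 <- defaultSVMParams(fs, 1L)
    p2 <- defaultSVMParams(fs, 2L)
    if (test == "kfold") {
      cv1 <- kfoldCV(feats, binary, k = k, seed = seed,
                     gamma = p1[["gamma"]], cost = p1[["cost"]])
      m1 <- cv1$foldMeans
      cv2 <- kfoldCV(featureValues(feats)[!negative, , drop = FALSE],
                     sub, k = k, seed = seed,
                     gamma = p2[["gamma"]], cost = p2[["cost"]])
      rep2 <- cv2$pooled
    } else {
      j1 <- jackknifeCV(feats, binary,
                        gamma = p1[["gamma"]], cost = p1[["cost"]])
      m1 <- reportMetrics(j1$pooled)
      j2 <- jackknifeCV(featureValues(feats)[!negative, , drop = FALSE],
                        sub, gamma = p2[["gamma"]], cost = p2[["cost"]])
      rep2 <- j2$pooled
    }
    m2 <- reportMetrics(rep2)
    level1 <- rbind(level1, data.frame(
      featureSet = fs, dimension = featureDim(fs),
      sens = m1[["sens"]], spec = m1[["spec"]], acc = m1[["acc"]],
      mcc = m1[["mcc"]], auc = m1[["auc"]]))
    level2 <- rbind(level2, data.frame(
      featureSet = fs, dimension = featureDim(fs),
      overallSens = m2[["sens"]], overallMCC = m2[["mcc"]],
      gamma = p2[["gamma"]], cost = p2[["cost"]]))
    perClass[[fs]] <- perClassTable(rep2)
  }
  structure(list(level1 = level1, level2 = level2, perClass = perClass,
                 test = test, k = as.integer(k), seed = as.integer(seed)),
            class = "nrProtocolReport")
}

#' @export
print.nrProtocolReport <- function(x, ...) {
  cat(sprintf("Feature-set comparison (%s%s)\n", x$test,
              if (x$test == "kfold") sprintf(", k = %d", x$k) else ""))
  cat("\nLevel 1 (NR vs non-NR):\n")
  l1 <- x$level1
  l1[3:7] <- lapply(l1[3:7], round, 4L)
  print(l1, row.names = FALSE)
  cat("\nLevel 2 (eight subfamilies):\n")
  l2 <- x$level2
  l2[3:4] <- lapply(l2[3:4], round, 4L)
  print(l2, row.names = FALSE)
  invisible(x)
}
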