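## Performance metrics: binary confusion metrics, per-class one-vs-rest
## multiclass metrics, and ROC/AUC.

.mcc <- function(TP, FP, TN, FN) {
  TP <- as.numeric(TP); FP <- as.numeric(FP)
  TN <- as.numeric(TN); FN <- as.numeric(FN)
  den <- (TP + FN) * (TP + FP) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)  # convention: MCC = 0 when any factor vanishes
  (TP * TN - FP * FN) / sqrt(den)
}

.metricsVector <- function(TP, FP, TN, FN, auc = NA_real_) {
  total <- TP + FP + TN + FN
  c(sens = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    spec = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
    acc  = (TP + TN) / total,
    mcc  = .mcc(TP, FP, TN, FN),
    auc  = auc)
}

#' Tally binary confusion counts
#'
#' @param truth,predicted Parallel vectors of binary labels.
#' @param positive The label counted as positive (default `"1"`).
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(truth, predicted, positive = "1") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  tp <- truth == positive
  pp <- predicted == positive
  c(TP = sum(tp & pp), FP = sum(!tp & pp),
    TN = sum(!tp & !pp), FN = sum(tp & !pp))
}

#' Binary classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`, with the
#' convention MCC = 0 whenever a factor under the square root is zero.
#'
#' @param counts Named vector with elements `TP`, `FP`, `TN`, `FN`, as
#'   produced by [confusionCounts()].  Alternatively pass the four counts
#'   via `TP`, `FP`, `TN`, `FN`.
#' @param TP,FP,TN,FN Individual counts (ignored when `counts` is
#'   given).
#' @param auc Optional AUC to carry in the report.
#' @return A [MetricsReport-class].
#' @examples
#' binaryMetrics(TP = 447, FN = 27, TN = 490, FP = 10)
#' @export
binaryMetrics <- function(counts = NULL, TP = 0, FP = 0, TN = 0, FN = 0,
                          auc = NA_real_) {
  if (!is.null(counts)) {
    stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
    TP <- counts[["TP"]]; FP <- counts[["FP"]]
    TN <- counts[["TN"]]; FN <- counts[["FN"]]
  }
  if (any(c(TP, FP, TN, FN) < 0) || TP + FP + TN + FN == 0)
    stop("confusion counts must be non-negative with a positive total")
  new("MetricsReport", task = "binary",
      metrics = .metricsVector(TP, FP, TN, FN, auc),
      counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
      perClass = data.frame())
}

#' Named metric values of a report
#'
#' @param report A [MetricsReport-class].
#' @return Named numeric vector `sens`, `spec`, `acc`, `mcc`, `auc`.
#' @export
reportMetrics <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  report@metrics
}

#' Per-class counts of a multiclass report
#'
#' @param report A [MetricsReport-class] from [perClassMetrics()].
#' @return Data frame with one row per class: `class`, `N`, `TP`, `TN`,
#'   `FP`, `FN`, `sens`, `spec`, `acc`, `mcc`.
#' @export
perClassTable <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  report@perClass
}

#' Multiclass per-class and overall metrics
#'
#' For each class i, one-vs-rest counts are derived from the class sizes
#' and the misassignments: `TP(i)` is the number of class-i samples
#' predicted as class i, `FN(i)` the class-i samples predicted
#' elsewhere, `FP(i)` the non-members predicted as i, and `TN(i)` the
#' remaining non-members.  Per-class metrics follow the binary formulas.
#' Overall sensitivity is the pooled rate `sum TP(i) / sum N(i)`;
#' overall specificity, accuracy and MCC are computed from the
#' micro-pooled one-vs-rest counts summed over classes.
#'
#' @param truth,predicted Parallel label vectors.
#' @param classes Class labels defining the order of the per-class
#'   table; defaults to the sorted union of `truth`.  `predicted` may
#'   additionally contain labels outside `classes` (e.g. a rejection
#'   class); such predictions count as misses for the true class.
#' @return A [MetricsReport-class]; the per-class table is available via
#'   [perClassTable()].
#' @examples
#' truth <- rep(c("NR1", "NR2"), c(4, 3))
#' pred  <- c("NR1", "NR1", "NR1", "NR2", "NR2", "NR2", "NR2")
#' reportMetrics(perClassMetrics(truth, pred))["sens"]
#' @export
perClassMetrics <- function(truth, predicted, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- sort(unique(truth))
  if (!length(classes)) stop("classes must be non-empty")
  if (!all(truth %in% classes))
    stop("true label(s) outside the declared classes: ",
         paste(setdiff(truth, classes), collapse = ", "))
  rows <- lapply(classes, function(cl) {
    inClass <- truth == cl
    Nplus <- sum(inClass)
    Nminus <- sum(!inClass)
    missesOut <- sum(inClass & predicted != cl)
    missesIn <- sum(!inClass & predicted == cl)
    TP <- Nplus - missesOut
    TN <- Nminus - missesIn
    m <- .metricsVector(TP, missesIn, TN, missesOut)
    # .metricsVector signature is (TP, FP, TN, FN)
    data.frame(class = cl, N = Nplus, TP = TP, TN = TN,
               FP = missesIn, FN = missesOut,
               sens = m[["sens"]], spec = m[["spec"]],
               acc = m[["acc"]], mcc = m[["mcc"]])
  })
  pc <- do.call(rbind, rows)
  TPs <- sum(pc$TP); FPs <- sum(pc$FP); TNs <- sum(pc$TN); FNs <- sum(pc$FN)
  overall <- .metricsVector(TPs, FPs, TNs, FNs)
  overall["sens"] <- TPs / sum(pc$N)  # pooled correct-classification rate
  new("MetricsReport", task = "multiclass", metrics = overall,
      counts = c(TP = TPs, FP = FPs, TN = TNs, FN = FNs),
      perClass = pc)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney probability that a randomly chosen
#' positive receives a higher score than a randomly chosen negative,
#' with ties counted 1/2 (computed from mid-ranks).  The curve lists
#' `(FPR, TPR)` at every distinct score threshold, from `(0, 0)` to
#' `(1, 1)`.
#'
#' @param scores Real-valued decision scores (higher = more positive).
#' @param labels Parallel binary labels.
#' @param positive Label counted as positive (default `"1"`).
#' @return List with elements `auc` (numeric scalar) and `curve` (data
#'   frame with columns `threshold`, `fpr`, `tpr`).
#' @examples
#' rocAuc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))$auc  # 0.75
#' @export
rocAuc <- function(scores, labels, positive = "1") {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores)  # mid-ranks give the tie-1/2 convention
  auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  last <- !duplicated(scores[ord], fromLast = TRUE)  # one point per threshold
  curve <- data.frame(threshold = c(Inf, scores[ord][last]),
                      fpr = c(0, fp[last] / nNeg),
                      tpr = c(0, tp[last] / nPos))
  list(auc = auc, curve = curve)
}

#' Write a metrics report to disk
#'
#' @param report A [MetricsReport-class].
#' @param path Output path; format chosen by extension (`.json` for
#'   JSON, otherwise tab-delimited).
#' @return Invisibly, `path`.
#' @export
writeMetricsReport <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(task = report@task, metrics = as.list(report@metrics),
           counts = as.list(report@counts),
           perClass = report@perClass),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    m <- report@metrics
    writeLines(paste(names(m), collapse = "\t"), con)
    writeLines(paste(sprintf("%.4f", m), collapse = "\t"), con)
    if (nrow(report@perClass))
      utils::write.table(report@perClass, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  invisible(path)
}
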