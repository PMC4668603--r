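## Cross-validation: stratified k-fold and jackknife (leave-one-out).

#' Build (stratified) cross-validation folds
#'
#' Under stratification each class is shuffled separately (with the
#' given seed) and dealt round-robin into the k folds, so per-class fold
#' sizes differ by at most one; small classes simply miss from some
#' folds.  Without stratification the whole sample is shuffled and dealt.
#'
#' @param labels Vector of class labels, one per sample.
#' @param k Number of folds, `2 <= k <= N`.
#' @param seed Integer seed controlling the shuffle.
#' @param stratified Logical; default `TRUE`.
#' @return Integer vector of fold assignments in `1..k`, parallel to
#'   `labels` (named like `labels` when it has names).
#' @export
makeFolds <- function(labels, k, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k must not exceed the number of samples (", n, ")")
  folds <- integer(n)
  withSeed(seed, {
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  names(folds) <- names(labels)
  folds
}

.asFeatureMatrix <- function(features) {
  if (is(features, "ProteinFeatures")) featureValues(features)
  else as.matrix(features)
}

.featureSetOf <- function(features) {
  if (is(features, "ProteinFeatures")) featureSet(features) else "custom"
}

.resolveParams <- function(features, gamma, cost, level) {
  fs <- .featureSetOf(features)
  if (is.null(gamma) || is.null(cost)) {
    base <- sub("\\[.*$", "", fs)
    if (!base %in% featureSetNames())
      stop("gamma and cost must be given explicitly for feature set '",
           fs, "'")
    def <- defaultSVMParams(base, level)
    if (is.null(gamma)) gamma <- def[["gamma"]]
    if (is.null(cost)) cost <- def[["cost"]]
  }
  c(gamma = gamma, cost = cost)
}

# Predict labels and, for binary tasks, a real-valued score oriented
# towards `positive`.
.svmPredict <- function(model, newdata, positive = NULL) {
  pred <- stats::predict(model, newdata, decision.values = TRUE)
  scores <- NULL
  dv <- attr(pred, "decision.values")
  if (!is.null(positive) && !is.null(dv) && ncol(dv) == 1L) {
    pair <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]]
    scores <- if (pair[1L] == positive) dv[, 1L] else -dv[, 1L]
  }
  list(labels = as.character(pred), scores = scores)
}

#' Stratified k-fold cross-validation of a single SVM level
#'
#' Splits the samples into k (stratified) folds, trains an RBF-kernel
#' SVM on k-1 folds and evaluates on the held-out fold.  For binary
#' tasks (exactly two label levels) per-fold sensitivity, specificity,
#' accuracy, MCC and AUC are averaged arithmetically over folds
#' (`foldMeans`), and the predictions pooled over folds yield a second
#' report (`pooled`).  For multiclass tasks the pooled predictions feed
#' [perClassMetrics()] and `foldMeans` holds the mean per-fold overall
#' sensitivity and accuracy.
#'
#' @param features A [ProteinFeatures-class] or numeric matrix.
#' @param labels Parallel vector of class labels.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @param gamma,cost RBF-SVM hyperparameters; when `NULL` the defaults
#'   for the feature set are used ([defaultSVMParams()]).
#' @param stratified Logical, stratify folds by class (default `TRUE`).
#' @param positive Positive label for binary tasks (default `"1"`).
#' @return List with elements `foldMeans` (named numeric), `pooled`
#'   ([MetricsReport-class]), `perFold` (data frame), `folds` (integer
#'   fold assignments, for audit), `k`, `seed`, `task`.
#' @export
kfoldCV <- function(features, labels, k = 10L, seed = 1L,
                    gamma = NULL, cost = NULL, stratified = TRUE,
                    positive = "1") {
  m <- .asFeatureMatrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(m) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("cross-validation needs at least 2 classes")
  binary <- length(classes) == 2L && positive %in% classes
  level <- if (binary) 1L else 2L
  par <- .resolveParams(features, gamma, cost, level)
  folds <- makeFolds(labels, k, seed, stratified)
  predicted <- character(length(labels))
  scores <- rep(NA_real_, length(labels))
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- trainLevel(m[!test, , drop = FALSE], labels[!test],
                      gamma = par[["gamma"]], cost = par[["cost"]])
    out <- .svmPredict(fit, m[test, , drop = FALSE],
                       positive = if (binary) positive)
    predicted[test] <- out$labels
    if (binary && !is.null(out$scores)) scores[test] <- out$scores
    if (binary) {
      cc <- confusionCounts(labels[test], out$labels, positive)
      auc <- if (length(unique(labels[test])) == 2L)
        rocAuc(out$scores, labels[test], positive)$auc else NA_real_
      mv <- .metricsVector(cc[["TP"]], cc[["FP"]], cc[["TN"]], cc[["FN"]],
                           auc)
    } else {
      rep <- perClassMetrics(labels[test], predicted = out$labels,
                             classes = classes)
      mv <- reportMetrics(rep)
    }
    perFold[[f]] <- data.frame(fold = f, n = sum(test), t(mv))
  }
  perFold <- do.call(rbind, perFold)
  foldMeans <- colMeans(perFold[, c("sens", "spec", "acc", "mcc", "auc")],
                        na.rm = TRUE)
  pooled <- if (binary) {
    binaryMetrics(confusionCounts(labels, predicted, positive),
                  auc = rocAuc(scores, labels, positive)$auc)
  } else {
    perClassMetrics(labels, predicted, classes)
  }
  list(foldMeans = foldMeans, pooled = pooled, perFold = perFold,
       folds = folds, k = k, seed = as.integer(seed),
       task = if (binary) "binary" else "multiclass")
}

#' Jackknife (leave-one-out) cross-validation
#'
#' Each of the N samples is predicted by a model trained on the other
#' N - 1.  The procedure involves no randomness and always yields the
#' same result for a given dataset, regardless of input order; pooled
#' confusion counts over the N rounds are reported.
#'
#' @inheritParams kfoldCV
#' @return List with elements `pooled` ([MetricsReport-class]),
#'   `predicted` (character vector of leave-one-out predictions), and
#'   `task`.
#' @export
jackknifeCV <- function(features, labels, gamma = NULL, cost = NULL,
                        positive = "1") {
  m <- .asFeatureMatrix(features)
  labels <- as.character(labels)
  n <- nrow(m)
  stopifnot(n == length(labels))
  if (n < 3L) stop("jackknife needs at least 3 samples")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("cross-validation needs at least 2 classes")
  binary <- length(classes) == 2L && positive %in% classes
  par <- .resolveParams(features, gamma, cost, if (binary) 1L else 2L)
  predicted <- character(n)
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- trainLevel(m[-i, , drop = FALSE], labels[-i],
                      gamma = par[["gamma"]], cost = par[["cost"]])
    out <- .svmPredict(fit, m[i, , drop = FALSE],
                       positive = if (binary) positive)
    predicted[i] <- out$labels
    if (binary && !is.null(out$scores)) scores[i] <- out$scores
  }
  pooled <- if (binary) {
    binaryMetrics(confusionCounts(labels, predicted, positive),
                  auc = rocAuc(scores, labels, positive)$auc)
  } else {
    perClassMetrics(labels, predicted, classes)
  }
  names(predicted) <- rownames(m)
  list(pooled = pooled, predicted = predicted,
       task = if (binary) "binary" else "multiclass")
}
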