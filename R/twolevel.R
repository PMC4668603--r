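## The two-level cascade: a binary NR / non-NR classifier gating an
## eight-subfamily classifier.  Both levels are soft-margin SVMs with an
## RBF kernel (multiclass handled one-vs-one, the native libsvm scheme).
## Feature values are frequencies in [0, 1] and are used unscaled.

#' Train one SVM level
#'
#' Fits a soft-margin RBF-kernel SVM (`e1071::svm`, i.e. libsvm) on a
#' feature matrix.  Multiclass problems use the native one-vs-one
#' strategy.  Features are not rescaled.
#'
#' @param features A [ProteinFeatures-class] or numeric matrix
#'   (sequences in rows).
#' @param labels Parallel vector of class labels; at least two classes
#'   must be present.
#' @param gamma RBF kernel width, must be positive.
#' @param cost Soft-margin cost C, must be positive.
#' @return A fitted `e1071::svm` classifier exposing `predict()` with
#'   `decision.values = TRUE`.
#' @export
trainLevel <- function(features, labels, gamma, cost) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a single positive number")
  if (!is.numeric(cost) || length(cost) != 1L || cost <= 0)
    stop("cost must be a single positive number")
  m <- .asFeatureMatrix(features)
  labels <- factor(as.character(labels))
  if (nrow(m) != length(labels))
    stop("features and labels must be parallel")
  if (nlevels(labels) < 2L)
    stop("training requires at least two classes, found ",
         nlevels(labels))
  e1071::svm(x = m, y = labels, type = "C-classification",
             kernel = "radial", gamma = gamma, cost = cost,
             scale = FALSE)
}

#' Exhaustive grid search for (gamma, cost)
#'
#' Evaluates every grid point by mean k-fold cross-validation accuracy
#' on fixed folds (shared across grid points so scores are comparable)
#' and returns the winner.  Ties are broken by smaller cost, then
#' smaller gamma.
#'
#' @param features A [ProteinFeatures-class] or numeric matrix.
#' @param labels Parallel class labels.
#' @param gammaGrid,costGrid Non-empty numeric grids of candidate
#'   values.
#' @param k Number of CV folds (default 5); must be at least 2.
#' @param seed Seed for the fold shuffle.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return List with elements `gamma`, `cost` (the winner), `table`
#'   (data frame of all grid points with mean CV accuracy), `k`,
#'   `seed`.
#' @export
gridSearch <- function(features, labels, gammaGrid, costGrid, k = 5L,
                       seed = 1L, stratified = TRUE) {
  if (!length(gammaGrid) || !length(costGrid))
    stop("gammaGrid and costGrid must be non-empty")
  if (k < 2L) stop("k must be at least 2")
  m <- .asFeatureMatrix(features)
  labels <- as.character(labels)
  folds <- makeFolds(labels, k, seed, stratified)
  grid <- expand.grid(gamma = sort(gammaGrid), cost = sort(costGrid))
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- trainLevel(m[!test, , drop = FALSE], labels[!test],
                        gamma = grid$gamma[i], cost = grid$cost[i])
      pred <- .svmPredict(fit, m[test, , drop = FALSE])$labels
      correct <- correct + sum(pred == labels[test])
    }
    correct / length(labels)
  }, numeric(1L))
  best <- grid[order(-grid$accuracy, grid$cost, grid$gamma), ][1L, ]
  list(gamma = best$gamma, cost = best$cost, table = grid,
       k = as.integer(k), seed = as.integer(seed))
}

#' Train the two-level NR cascade
#'
#' Encodes the sequences once with the chosen feature set, trains the
#' binary level-1 classifier (NR = 1 vs non-NR = 0) on all samples, and
#' the level-2 subfamily classifier on the NR samples only.
#'
#' @param x An [Biostrings::AAStringSet] (validated sequences) or a
#'   [LabeledProteinSet-class]; in the latter case `labels` defaults to
#'   its stored labels.
#' @param labels Factor/character vector parallel to the sequences;
#'   `"non-NR"` (or `"0"`) marks negatives, any other value is taken as
#'   the subfamily label of a positive.
#' @param featureSet Feature-set name (default `"AAC+CTF"`, the
#'   best-performing combination).
#' @param level1Params,level2Params Named `(gamma, cost)` vectors;
#'   `NULL` uses [defaultSVMParams()] for the feature set.
#' @param cgrAlpha Twelve-group vertex alphabet used when the feature
#'   set includes CGR.
#' @param seed Integer seed recorded in the model (training itself is
#'   deterministic).
#' @return A [TwoLevelModel-class].
#' @export
trainTwoLevel <- function(x, labels = NULL, featureSet = "AAC+CTF",
                          level1Params = NULL, level2Params = NULL,
                          cgrAlpha = cgrAlphabet(), seed = 1L) {
  if (is(x, "LabeledProteinSet")) {
    if (is.null(labels)) labels <- classLabels(x)
    x <- sequences(x)
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.character(labels)
  stopifnot(length(x) == length(labels))
  fs <- normalizeFeatureSet(featureSet)
  if (is.null(level1Params)) level1Params <- defaultSVMParams(fs, 1L)
  if (is.null(level2Params)) level2Params <- defaultSVMParams(fs, 2L)
  feats <- computeFeatures(x, fs, cgrAlpha = cgrAlpha)
  m <- featureValues(feats)
  negative <- labels %in% c("non-NR", "0")
  binary <- ifelse(negative, "0", "1")
  if (!any(negative) || all(negative))
    stop("training needs both NR and non-NR samples")
  sub <- labels[!negative]
  if (length(unique(sub)) < 2L)
    stop("level 2 requires at least two subfamilies")
  level1 <- trainLevel(m, binary, gamma = level1Params[["gamma"]],
                       cost = level1Params[["cost"]])
  level2 <- trainLevel(m[!negative, , drop = FALSE], sub,
                       gamma = level2Params[["gamma"]],
                       cost = level2Params[["cost"]])
  new("TwoLevelModel", featureSet = fs,
      level1 = level1, level2 = level2,
      level1Params = c(gamma = level1Params[["gamma"]],
                       cost = level1Params[["cost"]]),
      level2Params = c(gamma = level2Params[["gamma"]],
                       cost = level2Params[["cost"]]),
      cgrAlphabet = cgrAlpha,
      subfamilies = sort(unique(sub)),
      seed = as.integer(seed),
      version = as.character(utils::packageVersion("NRCascade")))
}

#' Predict with the two-level cascade
#'
#' Each sequence is encoded once with the model's feature set.  Level 1
#' decides NR vs non-NR; sequences predicted non-NR are returned as
#' `"non-NR"` and never reach level 2, the rest receive a subfamily
#' label from level 2.
#'
#' @param model A [TwoLevelModel-class].
#' @param x An [Biostrings::AAStringSet], character vector,
#'   [LabeledProteinSet-class], or an already encoded
#'   [ProteinFeatures-class] whose feature set matches the model.
#' @return Named factor of predictions with levels
#'   `c("non-NR", <subfamilies>)`.
#' @export
predictTwoLevel <- function(model, x) {
  stopifnot(is(model, "TwoLevelModel"))
  if (is(x, "LabeledProteinSet")) x <- sequences(x)
  feats <- if (is(x, "ProteinFeatures")) {
    if (!identical(featureSet(x), model@featureSet))
      stop("feature set mismatch: model expects ", model@featureSet,
           ", got ", featureSet(x))
    x
  } else {
    computeFeatures(x, model@featureSet, cgrAlpha = model@cgrAlphabet)
  }
  m <- featureValues(feats)
  l1 <- .svmPredict(model@level1, m)$labels
  out <- rep("non-NR", nrow(m))
  pos <- l1 == "1"
  if (any(pos))
    out[pos] <- .svmPredict(model@level2,
                            m[pos, , drop = FALSE])$labels
  factor(stats::setNames(out, rownames(m)),
         levels = c("non-NR", model@subfamilies))
}

#' Save a trained cascade to disk
#'
#' The archive contains both classifiers, the encoder configuration,
#' seed and version stamp; [readTwoLevelModel()] restores it with
#' bit-identical predictions.
#'
#' @param model A [TwoLevelModel-class].
#' @param path Output path (an RDS archive).
#' @return Invisibly, `path`.
#' @export
saveTwoLevelModel <- function(model, path) {
  stopifnot(is(model, "TwoLevelModel"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a cascade saved by [saveTwoLevelModel()]
#'
#' @param path Path to the archive.
#' @return A [TwoLevelModel-class].
#' @export
readTwoLevelModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "TwoLevelModel"))
    stop("'", path, "' does not contain a TwoLevelModel")
  model
}
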