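## Feature significance: per-feature two-sided Wilcoxon rank-sum tests
## between two sample groups, p-value ranking, top-k selection and
## ablation.

#' Rank features by Wilcoxon rank-sum significance
#'
#' For every feature column, a two-sided Wilcoxon (Mann-Whitney)
#' rank-sum test compares its values between the two groups.  By default
#' the normal approximation with mid-rank tie correction is used
#' (frequency features contain massive zero ties, and the interesting
#' p-values are far below the reach of the exact distribution); an exact
#' test is available for very small groups.  Features are ranked by
#' ascending p-value, ties broken by ascending column index.  A census
#' of features significant at `alpha` is attached, both raw (as
#' conventionally reported) and Bonferroni-adjusted (an extension).
#'
#' @param groupPos,groupNeg Feature matrices (or
#'   [ProteinFeatures-class]) for the two groups; equal column
#'   dimension, at least 2 rows each.
#' @param alpha Significance threshold for the census (default 0.01).
#' @param exact Use the exact rank-sum distribution (only sensible when
#'   both groups have at most ~10 samples; default `FALSE`).
#' @return Data frame with one row per feature, sorted by significance:
#'   columns `rank`, `index` (original column), `label`, `p.value`.
#'   Attributes `nSignificant` and `nSignificantBonferroni` carry the
#'   census at `alpha`.
#' @export
rankFeatures <- function(groupPos, groupNeg, alpha = 0.01, exact = FALSE) {
  pos <- .asFeatureMatrix(groupPos)
  neg <- .asFeatureMatrix(groupNeg)
  if (ncol(pos) != ncol(neg))
    stop("groups have different feature dimensions: ", ncol(pos),
         " vs ", ncol(neg))
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stop("each group needs at least 2 samples")
  labels <- colnames(pos)
  if (is.null(labels)) labels <- sprintf("f%d", seq_len(ncol(pos)))
  p <- vapply(seq_len(ncol(pos)), function(j) {
    x <- pos[, j]; y <- neg[, j]
    if (all(x == x[1L]) && all(y == x[1L])) return(1)  # constant feature
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = exact, correct = FALSE)$p.value)
  }, numeric(1L))
  p[is.na(p)] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)  # keep p in (0, 1]
  ord <- order(p, seq_along(p))
  out <- data.frame(rank = seq_along(p), index = ord, label = labels[ord],
                    p.value = p[ord])
  attr(out, "alpha") <- alpha
  attr(out, "nSignificant") <- sum(p < alpha)
  attr(out, "nSignificantBonferroni") <-
    sum(stats::p.adjust(p, "bonferroni") < alpha)
  out
}

#' Select the top-k ranked features
#'
#' @param ranking Data frame from [rankFeatures()].
#' @param k Number of features to keep, `0 <= k <= dimension`.
#' @return Integer vector of the original column indices of the k most
#'   significant features (empty for `k = 0`).
#' @export
selectTopK <- function(ranking, k) {
  d <- nrow(ranking)
  if (k < 0L || k > d)
    stop("k must lie in 0..", d)
  ranking$index[seq_len(k)]
}

#' Complement of the top-k features
#'
#' The remaining features after the top-k most significant ones are
#' taken away (e.g. 343 CTF features minus the top 50 leaves 293).
#'
#' @inheritParams selectTopK
#' @return Integer vector of the retained column indices, in original
#'   column order.
#' @export
ablateTopK <- function(ranking, k) {
  top <- selectTopK(ranking, k)
  setdiff(sort(ranking$index), top)
}

#' Restrict a feature matrix to a column subset
#'
#' Keeps the given columns in their original relative order; the result
#' is tagged `"<set>[k]"` and accepted by all downstream training and
#' evaluation functions.
#'
#' @param features A [ProteinFeatures-class] or numeric matrix.
#' @param subset Non-empty integer vector of column indices.
#' @return Same type as `features`, reduced to `length(subset)` columns.
#' @export
projectFeatures <- function(features, subset) {
  if (!length(subset)) stop("subset must be non-empty")
  m <- .asFeatureMatrix(features)
  if (any(subset < 1L) || any(subset > ncol(m)))
    stop("subset indices must lie in 1..", ncol(m))
  subset <- sort(unique(as.integer(subset)))
  reduced <- m[, subset, drop = FALSE]
  if (!is(features, "ProteinFeatures")) return(reduced)
  tag <- if (length(subset) == ncol(m)) featureSet(features)
         else sprintf("%s[%d]", featureSet(features), length(subset))
  new("ProteinFeatures", values = reduced, featureSet = tag)
}

#' Write a feature ranking table
#'
#' Tab-delimited: rank, feature label, p-value in scientific notation.
#'
#' @param ranking Data frame from [rankFeatures()].
#' @param path Output path.
#' @param digits Significant digits for the p-value (default 3).
#' @return Invisibly, `path`.
#' @export
writeRanking <- function(ranking, path, digits = 3L) {
  out <- data.frame(rank = ranking$rank, feature = ranking$label,
                    p.value = formatC(ranking$p.value, format = "E",
                                      digits = digits - 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
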