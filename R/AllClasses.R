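#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   letterFrequency width
NULL

setOldClass("svm")

#' AminoAlphabet: a partition of the 20 standard residues
#'
#' An `AminoAlphabet` partitions the 20 standard amino acids into named,
#' disjoint groups.  Residues within a group are treated as
#' interchangeable by the encoders that consume the alphabet: the
#' seven-class partition drives the conjoint triad features and a
#' twelve-group partition assigns residues to the vertices of the chaos
#' game polygon.
#'
#' @slot name Short identifier of the partition.
#' @slot groups Named list; each element is a character vector of
#'   single-letter residue codes.  Groups must be pairwise disjoint and
#'   jointly cover all 20 residues.
#'
#' @seealso [ctfAlphabet()], [cgrAlphabet()], [readAlphabet()]
#' @export
setClass("AminoAlphabet",
  representation(name = "character", groups = "list"))

setValidity("AminoAlphabet", function(object) {
  g <- object@groups
  if (is.null(names(g)) || any(!nzchar(names(g))) || anyDuplicated(names(g)))
    return("groups must have unique, non-empty names")
  res <- unlist(g, use.names = FALSE)
  if (anyDuplicated(res))
    return("groups must be pairwise disjoint")
  if (!setequal(res, AA20))
    return("groups must jointly cover exactly the 20 standard residues")
  TRUE
})

#' ProteinFeatures: a feature matrix with a feature-set identity
#'
#' Rows are sequences (named by sequence id), columns are features.  All
#' values are frequencies in \[0, 1\].  The `featureSet` slot records
#' which of the seven encodings produced the matrix; a matrix restricted
#' to a column subset (see [projectFeatures()]) carries the tag
#' `"<set>[k]"` where `k` is the number of retained columns.
#'
#' @slot values Numeric matrix, sequences in rows.
#' @slot featureSet Canonical feature-set name, or a subset tag.
#' @export
setClass("ProteinFeatures",
  representation(values = "matrix", featureSet = "character"))

setValidity("ProteinFeatures", function(object) {
  v <- object@values
  fs <- object@featureSet
  if (length(fs) != 1L) return("featureSet must be a single string")
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v))) return("values must have row names (sequence ids)")
  if (anyNA(v) || any(v < -1e-9) || any(v > 1 + 1e-9))
    return("all feature values must lie in [0, 1]")
  if (fs %in% featureSetNames() && ncol(v) != featureDim(fs))
    return(sprintf("feature set %s requires %d columns, found %d",
                   fs, featureDim(fs), ncol(v)))
  TRUE
})

#' LabeledProteinSet: sequences with parallel class labels
#'
#' Couples an [Biostrings::AAStringSet] with a parallel factor of class
#' labels (binary or the eight NR subfamilies plus `"non-NR"`), plus
#' free-form metadata (for synthetic collections: the generating
#' specification and the planted motifs).
#'
#' @slot sequences `AAStringSet` of validated protein sequences.
#' @slot labels Factor parallel to `sequences`.
#' @slot metadata List of provenance information.
#' @export
setClass("LabeledProteinSet",
  representation(sequences = "AAStringSet", labels = "factor",
                 metadata = "list"))

setValidity("LabeledProteinSet", function(object) {
  if (length(object@sequences) != length(object@labels))
    return("sequences and labels must have identical length")
  if (anyNA(object@labels))
    return("labels must not contain NA")
  TRUE
})

#' TwoLevelModel: the trained NR prediction cascade
#'
#' Holds the binary level-1 classifier (NR vs non-NR), the level-2
#' subfamily classifier, and the encoder configuration both were trained
#' with, so that prediction can encode raw sequences consistently.
#'
#' @slot featureSet Canonical feature-set name used by both levels.
#' @slot level1,level2 Trained `e1071::svm` objects.
#' @slot level1Params,level2Params Named `(gamma, cost)` vectors.
#' @slot cgrAlphabet The 12-group [AminoAlphabet-class] used for CGR
#'   encoding (present even when the feature set omits CGR).
#' @slot subfamilies Character vector of level-2 class labels.
#' @slot seed Integer seed recorded at training time.
#' @slot version Package version stamp.
#' @export
setClass("TwoLevelModel",
  representation(featureSet = "character",
                 level1 = "svm", level2 = "svm",
                 level1Params = "numeric", level2Params = "numeric",
                 cgrAlphabet = "AminoAlphabet",
                 subfamilies = "character",
                 seed = "integer", version = "character"))

#' MetricsReport: classification performance summary
#'
#' Sensitivity, specificity, accuracy and Matthews correlation
#' coefficient (plus AUC when decision scores are available) for a binary
#' task, or per-class one-vs-rest metrics plus micro-pooled overall
#' metrics for a multiclass task.
#'
#' @slot task `"binary"` or `"multiclass"`.
#' @slot metrics Named numeric: `sens`, `spec`, `acc`, `mcc`, `auc`
#'   (`auc` is `NA` when undefined).
#' @slot counts Named numeric confusion counts `TP`, `FP`, `TN`, `FN`
#'   (for multiclass: micro-pooled one-vs-rest counts).
#' @slot perClass Data frame of per-class counts and metrics (empty for
#'   binary tasks).
#' @export
setClass("MetricsReport",
  representation(task = "character", metrics = "numeric",
                 counts = "numeric", perClass = "data.frame"))

setValidity("MetricsReport", function(object) {
  need <- c("sens", "spec", "acc", "mcc", "auc")
  if (!all(need %in% names(object@metrics)))
    return("metrics must contain sens, spec, acc, mcc, auc")
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts)))
    return("counts must contain TP, FP, TN, FN")
  TRUE
})
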