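#' Number of groups in an alphabet
#' @param x An [AminoAlphabet-class].
#' @return Integer.
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' Group labels of an alphabet
#' @param x An [AminoAlphabet-class].
#' @return Character vector of group names in vertex/class order.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Residue-to-group lookup
#' @param x An [AminoAlphabet-class].
#' @return Named integer vector mapping each residue to its 1-based
#'   group index.
#' @export
setGeneric("classOf", function(x) standardGeneric("classOf"))

#' Feature-set identity of a feature matrix or model
#' @param x A [ProteinFeatures-class] or [TwoLevelModel-class].
#' @return Character scalar.
#' @export
setGeneric("featureSet", function(x) standardGeneric("featureSet"))

#' Numeric feature matrix
#' @param x A [ProteinFeatures-class].
#' @return Numeric matrix (sequences in rows).
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Sequences of a labeled collection
#' @param x A [LabeledProteinSet-class].
#' @return An [Biostrings::AAStringSet].
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Class labels of a labeled collection
#' @param x A [LabeledProteinSet-class].
#' @return Factor parallel to [sequences()].
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Collection metadata
#' @param x A [LabeledProteinSet-class].
#' @return List.
#' @export
setGeneric("collectionInfo", function(x) standardGeneric("collectionInfo"))

#' @describeIn nGroups Number of residue groups.
#' @export
setMethod("nGroups", "AminoAlphabet", function(x) length(x@groups))

#' @describeIn groupLabels Group names in order.
#' @export
setMethod("groupLabels", "AminoAlphabet", function(x) names(x@groups))

#' @describeIn classOf Residue lookup table.
#' @export
setMethod("classOf", "AminoAlphabet", function(x) {
  idx <- rep.int(seq_along(x@groups), lengths(x@groups))
  stats::setNames(idx, unlist(x@groups, use.names = FALSE))
})

#' @describeIn featureSet Identity of a feature matrix.
#' @export
setMethod("featureSet", "ProteinFeatures", function(x) x@featureSet)

#' @describeIn featureSet Feature set a cascade was trained on.
#' @export
setMethod("featureSet", "TwoLevelModel", function(x) x@featureSet)

#' @describeIn featureValues Extract the matrix.
#' @export
setMethod("featureValues", "ProteinFeatures", function(x) x@values)

#' @describeIn sequences Sequences slot.
#' @export
setMethod("sequences", "LabeledProteinSet", function(x) x@sequences)

#' @describeIn classLabels Labels slot.
#' @export
setMethod("classLabels", "LabeledProteinSet", function(x) x@labels)

#' @describeIn collectionInfo Metadata slot.
#' @export
setMethod("collectionInfo", "LabeledProteinSet", function(x) x@metadata)

#' @export
setMethod("length", "LabeledProteinSet", function(x) length(x@sequences))

#' @export
setMethod("dim", "ProteinFeatures", function(x) dim(x@values))

setMethod("show", "AminoAlphabet", function(object) {
  cat(sprintf("AminoAlphabet '%s' with %d groups:\n", object@name,
              nGroups(object)))
  for (i in seq_along(object@groups))
    cat(sprintf("  %2d %-6s {%s}\n", i, names(object@groups)[i],
                paste(object@groups[[i]], collapse = ",")))
})

setMethod("show", "ProteinFeatures", function(object) {
  cat(sprintf("ProteinFeatures: %d sequences x %d features (%s)\n",
              nrow(object@values), ncol(object@values), object@featureSet))
})

setMethod("show", "LabeledProteinSet", function(object) {
  cat(sprintf("LabeledProteinSet with %d sequences\n", length(object)))
  print(table(object@labels))
})

setMethod("show", "TwoLevelModel", function(object) {
  cat("TwoLevelModel (NR cascade)\n")
  cat(sprintf("  feature set : %s (%d-d)\n", object@featureSet,
              featureDim(object@featureSet)))
  cat(sprintf("  level 1     : binary RBF-SVM, gamma = %g, cost = %g\n",
              object@level1Params["gamma"], object@level1Params["cost"]))
  cat(sprintf("  level 2     : %d-class RBF-SVM, gamma = %g, cost = %g\n",
              length(object@subfamilies),
              object@level2Params["gamma"], object@level2Params["cost"]))
  cat(sprintf("  seed        : %d\n", object@seed))
})

setMethod("show", "MetricsReport", function(object) {
  m <- object@metrics
  cat(sprintf("MetricsReport (%s)\n", object@task))
  cat(sprintf("  Sens = %.4f  Spec = %.4f  Acc = %.4f  MCC = %.4f",
              m["sens"], m["spec"], m["acc"], m["mcc"]))
  if (!is.na(m["auc"])) cat(sprintf("  AUC = %.4f", m["auc"]))
  cat("\n")
  if (nrow(object@perClass)) {
    cat("  per-class:\n")
    pc <- object@perClass
    num <- vapply(pc, is.numeric, logical(1L)) &
      names(pc) %in% c("sens", "spec", "acc", "mcc")
    pc[num] <- lapply(pc[num], round, 4L)
    print(pc, row.names = FALSE)
  }
})
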