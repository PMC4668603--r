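## Internal constants and helpers shared across modules.

# The 20 standard residues in the fixed (alphabetical) order used for AAC.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Block composition of the seven supported feature sets, keyed by their
# canonical display names.  Blocks are always concatenated in the order
# AAC, CGR, CTF regardless of how the user spells the set.
.featureSetBlocks <- list(
  "AAC"         = "AAC",
  "CGR"         = "CGR",
  "CTF"         = "CTF",
  "AAC+CGR"     = c("AAC", "CGR"),
  "AAC+CTF"     = c("AAC", "CTF"),
  "CTF+CGR"     = c("CGR", "CTF"),
  "CTF+CGR+AAC" = c("AAC", "CGR", "CTF")
)

.blockDims <- c(AAC = 20L, CGR = 24L, CTF = 343L)

#' Canonical feature-set names
#'
#' @return Character vector of the seven supported feature-set names.
#' @export
featureSetNames <- function() names(.featureSetBlocks)

#' Normalize a feature-set name
#'
#' Maps any spelling such as `"aac+ctf"`, `"ctf + aac"` or `"AAC+CGR+CTF"`
#' to the canonical display name of the corresponding feature set.
#'
#' @param featureSet A single character string naming one of the seven
#'   feature sets; blocks may appear in any order and case.
#' @return The canonical name, one of [featureSetNames()].
#' @examples
#' normalizeFeatureSet("ctf+aac")   # "AAC+CTF"
#' normalizeFeatureSet("aac+cgr+ctf")
#' @export
normalizeFeatureSet <- function(featureSet) {
  stopifnot(is.character(featureSet), length(featureSet) == 1L)
  blocks <- toupper(trimws(strsplit(featureSet, "+", fixed = TRUE)[[1]]))
  blocks <- blocks[nzchar(blocks)]
  bad <- setdiff(blocks, names(.blockDims))
  if (length(bad) || !length(blocks) || anyDuplicated(blocks))
    stop("unknown feature set: '", featureSet,
         "' (blocks must be drawn from AAC, CGR, CTF)")
  blocks <- names(.blockDims)[names(.blockDims) %in% blocks]  # canonical order
  for (nm in names(.featureSetBlocks))
    if (identical(.featureSetBlocks[[nm]], blocks)) return(nm)
  stop("unknown feature set: '", featureSet, "'")  # unreachable
}

#' Dimension of a feature set
#'
#' @param featureSet Feature-set name (any spelling accepted by
#'   [normalizeFeatureSet()]).
#' @return Integer dimension: 20, 24, 343, 44, 363, 367 or 387.
#' @examples
#' featureDim("AAC+CTF")  # 363
#' @export
featureDim <- function(featureSet) {
  fs <- normalizeFeatureSet(featureSet)
  sum(.blockDims[.featureSetBlocks[[fs]]])
}

featureSetBlocks <- function(featureSet)
  .featureSetBlocks[[normalizeFeatureSet(featureSet)]]

# Tuned (gamma, cost) defaults per feature set.  The subfamily-level values
# are the published optima for each set; the binary level reuses them except
# for AAC+CTF, where a separately tuned binary optimum is available.
.svmDefaultsLevel2 <- list(
  "AAC"         = c(gamma = 2.0231, cost = 71.8882),
  "CGR"         = c(gamma = 1.0098, cost = 77.9671),
  "CTF"         = c(gamma = 0.0192, cost = 11.0849),
  "AAC+CGR"     = c(gamma = 2.5595, cost = 13.0576),
  "AAC+CTF"     = c(gamma = 0.0159, cost = 10.3440),
  "CTF+CGR"     = c(gamma = 0.0015, cost = 104.92),
  "CTF+CGR+AAC" = c(gamma = 0.0138, cost = 11.6455)
)

#' Default RBF-SVM hyperparameters for a feature set
#'
#' Returns the tuned `(gamma, cost)` pair used by default for the given
#' feature set and cascade level.  Level 1 is the binary NR / non-NR
#' classifier, level 2 the eight-subfamily classifier.
#'
#' @param featureSet Feature-set name.
#' @param level Cascade level, 1 or 2.
#' @return Named numeric vector with elements `gamma` and `cost`.
#' @export
defaultSVMParams <- function(featureSet, level = 1L) {
  fs <- normalizeFeatureSet(featureSet)
  stopifnot(level %in% c(1L, 2L))
  if (level == 1L && fs == "AAC+CTF")
    return(c(gamma = 0.1899, cost = 10.1197))
  .svmDefaultsLevel2[[fs]]
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream.
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}
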