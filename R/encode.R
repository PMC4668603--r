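## Sequence encoders: amino acid composition (AAC) and conjoint triad
## features (CTF).  The chaos game representation lives in cgr.R.

.asCharSeqs <- function(x) {
  seqs <- toupper(as.character(x))
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  bad <- grepl(sprintf("[^%s]", paste(AA20, collapse = "")), seqs)
  if (any(bad))
    stop("non-standard residues in record(s): ",
         paste(names(seqs)[bad], collapse = ", "),
         " (run validateProteins() first)")
  seqs
}

#' Amino acid composition (AAC, 20-d)
#'
#' The normalized frequency `f_i = n_i / L` of each of the 20 residues,
#' in fixed alphabetical order of the one-letter codes
#' (A, C, D, ..., Y).  Components of each row sum to 1.
#'
#' @param x An [Biostrings::AAStringSet] or (named) character vector of
#'   validated sequences; every sequence must have length at least 1.
#' @return A [ProteinFeatures-class] with 20 columns.
#' @examples
#' featureValues(computeAAC(c(s1 = "MKV")))[, c("K", "M", "V")]
#' @export
computeAAC <- function(x) {
  seqs <- .asCharSeqs(x)
  if (any(!nzchar(seqs)))
    stop("empty sequence(s): ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  aa <- Biostrings::AAStringSet(seqs)
  counts <- Biostrings::letterFrequency(aa, AA20)
  m <- counts / Biostrings::width(aa)
  dimnames(m) <- list(names(seqs), AA20)
  new("ProteinFeatures", values = m, featureSet = "AAC")
}

#' Reduce a sequence to alphabet class indices
#'
#' Replaces each residue by the 1-based index of its group in the
#' alphabet, so that residues in the same group become indistinguishable.
#'
#' @param x A single sequence (character scalar or `AAString`-like).
#' @param alphabet An [AminoAlphabet-class]; default the seven-class
#'   triad alphabet.
#' @return Integer vector of class indices, same length as the sequence.
#' @examples
#' reduceSequence("RKDE")  # 5 5 6 6
#' @export
reduceSequence <- function(x, alphabet = ctfAlphabet()) {
  s <- toupper(as.character(x))
  stopifnot(length(s) == 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  lut <- classOf(alphabet)
  idx <- unname(lut[chars])
  if (anyNA(idx)) {
    at <- which(is.na(idx))[1L]
    stop("residue '", chars[at], "' at position ", at,
         " is outside alphabet '", alphabet@name, "'")
  }
  idx
}

#' Triad bin index
#'
#' Maps an ordered triple of class indices in `1..7` to its bin in
#' `1..343` via `(c1-1)*49 + (c2-1)*7 + c3` (lexicographic, last class
#' fastest).  The mapping is bijective.
#'
#' @param c1,c2,c3 Integer vectors of class indices in `1..7`.
#' @return Integer vector of bin indices in `1..343`.
#' @examples
#' triadIndex(1, 1, 1)  # 1
#' triadIndex(7, 7, 7)  # 343
#' @export
triadIndex <- function(c1, c2, c3) {
  c1 <- as.integer(c1); c2 <- as.integer(c2); c3 <- as.integer(c3)
  if (anyNA(c(c1, c2, c3)) || any(c(c1, c2, c3) < 1L) ||
      any(c(c1, c2, c3) > 7L))
    stop("class indices must lie in 1..7")
  (c1 - 1L) * 49L + (c2 - 1L) * 7L + c3
}

#' Labels of the 343 triad bins
#'
#' @param alphabet The seven-class [AminoAlphabet-class].
#' @return Character vector of 343 labels such as `"C-RK-AGV"`, in
#'   [triadIndex()] order.
#' @export
triadLabels <- function(alphabet = ctfAlphabet()) {
  g <- groupLabels(alphabet)
  stopifnot(length(g) == 7L)
  idx <- expand.grid(c3 = 1:7, c2 = 1:7, c1 = 1:7)  # c3 fastest
  paste(g[idx$c1], g[idx$c2], g[idx$c3], sep = "-")
}

#' Triad bin of a motif string
#'
#' Accepts either a reduced-class motif such as `"C-RK-AGV"` (three group
#' labels joined by `-`) or a literal residue 3-mer such as `"CKA"`.
#'
#' @param motif Character vector of motifs.
#' @param alphabet The seven-class [AminoAlphabet-class].
#' @return Integer vector of bin indices in `1..343`.
#' @export
motifTriadIndex <- function(motif, alphabet = ctfAlphabet()) {
  g <- groupLabels(alphabet)
  lut <- classOf(alphabet)
  vapply(motif, function(m) {
    if (grepl("-", m, fixed = TRUE)) {
      parts <- strsplit(m, "-", fixed = TRUE)[[1]]
      if (length(parts) != 3L || !all(parts %in% g))
        stop("malformed reduced-class motif: '", m, "'")
      cls <- match(parts, g)
    } else {
      chars <- strsplit(toupper(m), "", fixed = TRUE)[[1]]
      if (length(chars) != 3L || anyNA(lut[chars]))
        stop("malformed literal motif: '", m, "'")
      cls <- unname(lut[chars])
    }
    triadIndex(cls[1L], cls[2L], cls[3L])
  }, integer(1L), USE.NAMES = FALSE)
}

#' Conjoint triad features (CTF, 343-d)
#'
#' Each sequence is reduced to the seven-class alphabet; a width-3 window
#' slides over it with step 1, incrementing the [triadIndex()] bin of
#' each of the `L - 2` triads; bins are normalized by `L - 2`
#' (`f_i = n_i / (L - 2)`), so each row sums to 1.  Sequences shorter
#' than 3 residues are rejected.
#'
#' @param x An [Biostrings::AAStringSet] or (named) character vector of
#'   validated sequences, each of length at least 3.
#' @param alphabet The seven-class [AminoAlphabet-class].
#' @return A [ProteinFeatures-class] with 343 columns named by triad
#'   labels (e.g. `"C-RK-AGV"`).
#' @examples
#' pf <- computeCTF(c(s1 = "ACDA"))
#' featureValues(pf)[, c("AGV-C-DE", "C-DE-AGV")]
#' @export
computeCTF <- function(x, alphabet = ctfAlphabet()) {
  seqs <- .asCharSeqs(x)
  short <- nchar(seqs) < 3L
  if (any(short))
    stop("CTF requires minimum length 3; too short: ",
         paste(names(seqs)[short], collapse = ", "))
  lut <- classOf(alphabet)
  m <- t(vapply(seqs, function(s) {
    r <- unname(lut[strsplit(s, "", fixed = TRUE)[[1]]])
    L <- length(r)
    idx <- (r[1:(L - 2L)] - 1L) * 49L + (r[2:(L - 1L)] - 1L) * 7L + r[3:L]
    tabulate(idx, 343L) / (L - 2L)
  }, numeric(343L)))
  dimnames(m) <- list(names(seqs), triadLabels(alphabet))
  new("ProteinFeatures", values = m, featureSet = "CTF")
}

#' Concatenate feature blocks
#'
#' Blocks must encode the same sequences (identical row ids) and are
#' concatenated in the canonical order AAC, CGR, CTF; the result is
#' tagged with the canonical name of the combination.  A single block is
#' returned unchanged.
#'
#' @param blocks List of [ProteinFeatures-class] objects whose feature
#'   sets are distinct elementary blocks (AAC, CGR, CTF).
#' @return A [ProteinFeatures-class] of the combined feature set.
#' @export
combineFeatures <- function(blocks) {
  if (is(blocks, "ProteinFeatures")) return(blocks)
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  sets <- vapply(blocks, featureSet, "")
  if (!all(sets %in% names(.blockDims)) || anyDuplicated(sets))
    stop("blocks must be distinct elementary feature sets (AAC, CGR, CTF)")
  if (length(blocks) == 1L) return(blocks[[1L]])
  blocks <- blocks[order(match(sets, names(.blockDims)))]
  ids <- rownames(featureValues(blocks[[1L]]))
  for (b in blocks[-1L])
    if (!identical(rownames(featureValues(b)), ids))
      stop("all blocks must encode the same sequences in the same order")
  name <- normalizeFeatureSet(
    paste(sort(vapply(blocks, featureSet, "")), collapse = "+"))
  new("ProteinFeatures",
      values = do.call(cbind, lapply(blocks, featureValues)),
      featureSet = name)
}

#' Encode sequences with any of the seven feature sets
#'
#' Computes the elementary blocks required by `featureSet` and
#' concatenates them in canonical order (AAC, CGR, CTF).
#'
#' @param x An [Biostrings::AAStringSet], character vector, or
#'   [LabeledProteinSet-class] of validated sequences.
#' @param featureSet Feature-set name (any spelling accepted by
#'   [normalizeFeatureSet()]).
#' @param ctfAlpha Seven-class alphabet for CTF.
#' @param cgrAlpha Twelve-group vertex alphabet for CGR.
#' @return A [ProteinFeatures-class] of dimension [featureDim()].
#' @examples
#' dim(computeFeatures(c(s1 = "MKVLAC"), "AAC+CTF"))  # 1 x 363
#' @export
computeFeatures <- function(x, featureSet = "AAC+CTF",
                            ctfAlpha = ctfAlphabet(),
                            cgrAlpha = cgrAlphabet()) {
  if (is(x, "LabeledProteinSet")) x <- sequences(x)
  fs <- normalizeFeatureSet(featureSet)
  blocks <- lapply(featureSetBlocks(fs), function(b)
    switch(b,
           AAC = computeAAC(x),
           CGR = computeCGR(x, alphabet = cgrAlpha),
           CTF = computeCTF(x, alphabet = ctfAlpha)))
  combineFeatures(blocks)
}
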