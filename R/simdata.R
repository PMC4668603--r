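## Synthetic labeled protein collections with planted, class-specific
## triad biases.  Sequences are drawn residue-by-residue from a
## background distribution; each class then receives copies of its
## planted 3-mer motifs written at random positions, at a rate
## proportional to the motif weight and the sequence length.  The
## resulting collections make every pipeline stage (encoding, cascade
## training, cross-validation, feature ranking) testable without any
## external dataset.

#' Generate a labeled synthetic protein collection
#'
#' For each class, `nPerClass[class]` sequences are generated: lengths
#' are uniform on `lengthRange`, residues are drawn i.i.d. from
#' `background`, and every motif of `motifs[[class]]` is written into
#' the sequence `round(weight * L / 100)` times at positions sampled
#' without replacement (the weight is the expected number of planted
#' copies per 100 residues).  Motifs given in reduced-class notation
#' (`"C-RK-AGV"`) are expanded to a random literal 3-mer consistent with
#' the classes at each insertion; literal 3-mers (`"CKA"`) are written
#' verbatim.  Generation is deterministic given `seed`.
#'
#' @param nPerClass Named vector of positive class sizes.
#' @param lengthRange Integer vector `c(min, max)` of sequence lengths,
#'   `min >= 3`.
#' @param background Probability vector over the 20 residues (in the
#'   alphabetical order of [computeAAC()]); default uniform.
#' @param motifs Named list (by class) of character vectors of motifs;
#'   classes absent from the list receive no planted motifs.
#' @param weights Named list or vector parallel to `motifs` giving the
#'   per-motif enrichment weight (recycled within a class; default 3).
#'   All weights must be at least 1.
#' @param seed Integer seed.
#' @return A [LabeledProteinSet-class]; `collectionInfo()` records the
#'   generating specification and the planted motifs.
#' @examples
#' x <- generateCollection(c(pos = 5, neg = 5), lengthRange = c(50, 80),
#'                         motifs = list(pos = "C-RK-AGV"), seed = 7)
#' table(classLabels(x))
#' @export
generateCollection <- function(nPerClass, lengthRange = c(120L, 400L),
                               background = NULL, motifs = list(),
                               weights = NULL, seed = 1L) {
  if (is.null(names(nPerClass)) || any(!nzchar(names(nPerClass))))
    stop("invalid nPerClass: classes must be named")
  if (any(nPerClass < 1L))
    stop("invalid nPerClass: all class sizes must be positive")
  lengthRange <- as.integer(lengthRange)
  if (length(lengthRange) != 2L || lengthRange[1L] < 3L ||
      lengthRange[2L] < lengthRange[1L])
    stop("invalid lengthRange: need min >= 3 and max >= min")
  if (is.null(background)) background <- rep(1 / 20, 20L)
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-8)
    stop("invalid background: need 20 probabilities summing to 1")
  bad <- setdiff(names(motifs), names(nPerClass))
  if (length(bad))
    stop("invalid motifs: unknown class(es) ", paste(bad, collapse = ", "))
  alpha <- ctfAlphabet()
  groups <- alpha@groups
  glabels <- groupLabels(alpha)
  wFor <- function(cl, nm) {
    w <- if (is.null(weights)) 3 else if (is.list(weights))
      (if (is.null(weights[[cl]])) 3 else weights[[cl]]) else weights
    w <- rep_len(w, nm)
    if (any(w < 1)) stop("invalid weights: enrichment weights must be >= 1")
    w
  }
  expandMotif <- function(m) {
    if (grepl("-", m, fixed = TRUE)) {
      parts <- strsplit(m, "-", fixed = TRUE)[[1]]
      if (length(parts) != 3L || !all(parts %in% glabels))
        stop("invalid motifs: malformed reduced-class motif '", m, "'")
      vapply(parts, function(p) {
        g <- groups[[match(p, glabels)]]
        g[sample.int(length(g), 1L)]
      }, "")
    } else {
      chars <- strsplit(toupper(m), "", fixed = TRUE)[[1]]
      if (length(chars) != 3L || !all(chars %in% AA20))
        stop("invalid motifs: malformed literal motif '", m, "'")
      chars
    }
  }
  seqs <- character(sum(nPerClass))
  ids <- character(sum(nPerClass))
  labs <- character(sum(nPerClass))
  withSeed(seed, {
    at <- 0L
    for (cl in names(nPerClass)) {
      clMotifs <- motifs[[cl]]
      clW <- if (length(clMotifs)) wFor(cl, length(clMotifs))
      for (i in seq_len(nPerClass[[cl]])) {
        at <- at + 1L
        L <- sample(seq.int(lengthRange[1L], lengthRange[2L]), 1L)
        chars <- sample(AA20, L, replace = TRUE, prob = background)
        if (length(clMotifs)) {
          copies <- pmax(0L, as.integer(round(clW * L / 100)))
          starts <- sample.int(L - 2L, min(sum(copies), L - 2L))
          s <- 0L
          for (j in seq_along(clMotifs)) {
            for (cp in seq_len(copies[j])) {
              s <- s + 1L
              if (s > length(starts)) break
              chars[starts[s] + 0:2] <- expandMotif(clMotifs[j])
            }
          }
        }
        seqs[at] <- paste(chars, collapse = "")
        ids[at] <- sprintf("%s_%03d", cl, i)
        labs[at] <- cl
      }
    }
  })
  new("LabeledProteinSet",
      sequences = Biostrings::AAStringSet(stats::setNames(seqs, ids)),
      labels = factor(labs, levels = names(nPerClass)),
      metadata = list(nPerClass = nPerClass, lengthRange = lengthRange,
                      background = background, motifs = motifs,
                      weights = weights, seed = as.integer(seed)))
}

# Subfamily-specific planted motifs of the default benchmark: two
# distinct reduced-class triads per subfamily, disjoint from the shared
# NR motifs.
.benchmarkSubfamilyMotifs <- list(
  NR1 = c("ILFP-ILFP-ILFP", "YMTS-ILFP-RK"),
  NR2 = c("YMTS-YMTS-YMTS", "HNQW-YMTS-RK"),
  NR3 = c("HNQW-HNQW-HNQW", "ILFP-HNQW-RK"),
  NR4 = c("RK-RK-RK",       "ILFP-YMTS-HNQW"),
  NR5 = c("DE-DE-DE",       "RK-DE-ILFP"),
  NR6 = c("C-C-C",          "DE-ILFP-YMTS"),
  NR7 = c("AGV-AGV-AGV",    "HNQW-DE-YMTS"),
  NR8 = c("ILFP-RK-DE",     "YMTS-HNQW-DE"))

# Reduced-class triads planted in every NR sequence; these are the
# features that discriminate NRs from non-NRs by construction.
.benchmarkSharedMotifs <- c("C-RK-AGV", "AGV-C-RK", "C-AGV-DE",
                            "DE-AGV-C")

#' The default synthetic benchmark collection
#'
#' A two-class collection shaped like the real NR training data: 474
#' positives split over the eight subfamilies in the proportions
#' 162, 140, 82, 23, 29, 7, 21, 10 (NR1..NR8), plus 500 negatives.  All
#' positives carry four shared planted triads (the NR signature used by
#' level 1); each subfamily additionally carries two subfamily-specific
#' triads (the signal used by level 2); negatives are pure background.
#' The planted biases are separable by construction, so a trained
#' cascade reaches high cross-validated accuracy on this collection.
#'
#' @param seed Integer seed.
#' @param scale Positive scaling factor applied to all class sizes
#'   (rounded, minimum 3 per class); `scale = 1` gives the full
#'   474 + 500 collection, smaller values give a cheaper replica with
#'   the same proportions.
#' @return A [LabeledProteinSet-class] with labels in
#'   `c("NR1", ..., "NR8", "non-NR")`.  `collectionInfo()$discriminative`
#'   names the four shared NR triads, `$subfamilyMotifs` the per-family
#'   ones.
#' @export
defaultBenchmark <- function(seed = 1L, scale = 1) {
  stopifnot(scale > 0)
  sizes <- c(NR1 = 162L, NR2 = 140L, NR3 = 82L, NR4 = 23L, NR5 = 29L,
             NR6 = 7L, NR7 = 21L, NR8 = 10L, "non-NR" = 500L)
  if (scale != 1)
    sizes[] <- pmax(3L, as.integer(round(sizes * scale)))
  motifs <- lapply(.benchmarkSubfamilyMotifs, function(m)
    c(.benchmarkSharedMotifs, m))
  weights <- lapply(motifs, function(m)
    c(rep(2, length(.benchmarkSharedMotifs)),
      rep(3, length(m) - length(.benchmarkSharedMotifs))))
  x <- generateCollection(sizes, lengthRange = c(120L, 400L),
                          motifs = motifs, weights = weights, seed = seed)
  x@metadata$discriminative <- .benchmarkSharedMotifs
  x@metadata$subfamilyMotifs <- .benchmarkSubfamilyMotifs
  x
}

#' Write a labeled collection as FASTA plus label file
#'
#' @param x A [LabeledProteinSet-class].
#' @param fasta,labels Output paths for the FASTA file and the
#'   two-column tab-delimited label file.
#' @return Invisibly, a character vector of the two paths.
#' @export
writeCollection <- function(x, fasta, labels) {
  stopifnot(is(x, "LabeledProteinSet"))
  writeProteinFasta(sequences(x), fasta)
  utils::write.table(
    data.frame(id = names(sequences(x)),
               label = as.character(classLabels(x))),
    labels, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(c(fasta = fasta, labels = labels))
}
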