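# Shared fixtures and independent oracles, built in code.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Random valid protein sequences (character vector with ids).
randomSeqs <- function(n, minLen = 3L, maxLen = 50L, seed = 1L) {
  set.seed(seed)
  lens <- sample(minLen:maxLen, n, replace = TRUE)
  stats::setNames(
    vapply(lens, function(L) paste(sample(AA, L, TRUE), collapse = ""), ""),
    sprintf("r%03d", seq_len(n)))
}

# Independent CTF oracle: materialize every reduced 3-mer of a sequence
# as a string key and count in a dictionary.
ctfOracleCounts <- function(seq) {
  classes <- list(AGV = c("A", "G", "V"), ILFP = c("I", "L", "F", "P"),
                  YMTS = c("Y", "M", "T", "S"), HNQW = c("H", "N", "Q", "W"),
                  RK = c("R", "K"), DE = c("D", "E"), C = "C")
  lut <- character(0)
  for (k in seq_along(classes)) lut[classes[[k]]] <- as.character(k)
  chars <- strsplit(seq, "")[[1]]
  red <- lut[chars]
  L <- length(red)
  keys <- paste(red[1:(L - 2)], red[2:(L - 1)], red[3:L], sep = ".")
  table(keys) / (L - 2)
}

# Brute-force pairwise AUC oracle: P(score_pos > score_neg) + P(==)/2.
aucOracle <- function(scores, labels, positive = "1") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Two well-separated planar clusters for SVM unit tests.
separableClusters <- function(nPerClass = 20L, seed = 1L, gap = 4) {
  set.seed(seed)
  m <- rbind(matrix(rnorm(nPerClass * 2, 0), ncol = 2),
             matrix(rnorm(nPerClass * 2, gap), ncol = 2))
  rownames(m) <- sprintf("p%02d", seq_len(2 * nPerClass))
  list(x = m, y = rep(c("0", "1"), each = nPerClass))
}

# A small, strongly separable labeled collection for cascade tests.
smallCascadeCollection <- function(seed = 1L) {
  generateCollection(
    c(NR1 = 18L, NR3 = 18L, "non-NR" = 24L),
    lengthRange = c(60L, 120L),
    motifs = list(NR1 = c("C-RK-AGV", "ILFP-ILFP-ILFP"),
                  NR3 = c("C-RK-AGV", "HNQW-HNQW-HNQW")),
    weights = list(NR1 = c(4, 5), NR3 = c(4, 5)),
    seed = seed)
}

writeFastaFile <- function(lines, path = tempfile(fileext = ".fa")) {
  writeLines(lines, path)
  path
}
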