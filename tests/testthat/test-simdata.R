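test_that("generation is deterministic given the seed", {
  spec <- list(n = c(a = 10L, b = 10L), motifs = list(a = "C-RK-AGV"))
  x1 <- generateCollection(spec$n, motifs = spec$motifs, seed = 7)
  x2 <- generateCollection(spec$n, motifs = spec$motifs, seed = 7)
  expect_identical(as.character(sequences(x1)), as.character(sequences(x2)))
  expect_identical(classLabels(x1), classLabels(x2))
  x3 <- generateCollection(spec$n, motifs = spec$motifs, seed = 8)
  expect_false(identical(as.character(sequences(x1)),
                         as.character(sequences(x3))))
})

test_that("class sizes and labels are exactly as requested", {
  n <- stats::setNames(rep(30L, 8), paste0("NR", 1:8))
  x <- generateCollection(n, lengthRange = c(50L, 80L), seed = 1)
  expect_length(x, 240L)
  expect_equal(as.vector(table(classLabels(x))), rep(30L, 8))
  expect_true(all(startsWith(names(sequences(x)),
                             as.character(classLabels(x)))))
})

test_that("generated sequences always pass strict validation", {
  x <- generateCollection(c(a = 15L, b = 15L), lengthRange = c(3L, 200L),
                          motifs = list(a = c("C-RK-AGV", "CKA")),
                          seed = 5)
  expect_silent(validateProteins(sequences(x), policy = "strict"))
  lens <- Biostrings::width(sequences(x))
  expect_true(all(lens >= 3L & lens <= 200L))
})

test_that("invalid specifications are rejected with the field named", {
  expect_error(generateCollection(c(10, 10)), "nPerClass")
  expect_error(generateCollection(c(a = 0L)), "nPerClass")
  expect_error(generateCollection(c(a = 5L), lengthRange = c(2L, 10L)),
               "lengthRange")
  expect_error(generateCollection(c(a = 5L), background = rep(0.1, 5)),
               "background")
  expect_error(generateCollection(c(a = 5L), motifs = list(zz = "C-RK-AGV")),
               "motifs")
  expect_error(generateCollection(c(a = 5L), motifs = list(a = "C-RK")),
               "motifs")
  expect_error(generateCollection(c(a = 5L), motifs = list(a = "C-RK-AGV"),
                                  weights = list(a = 0.5)), "weights")
})

test_that("planted triads raise their CTF component mean in the carrier class", {
  bin <- motifTriadIndex("C-RK-AGV")
  deltas <- vapply(1:50, function(s) {
    x <- generateCollection(c(pos = 8L, neg = 8L),
                            lengthRange = c(60L, 120L),
                            motifs = list(pos = "C-RK-AGV"), seed = s)
    v <- featureValues(computeCTF(sequences(x)))
    lab <- classLabels(x)
    mean(v[lab == "pos", bin]) - mean(v[lab == "neg", bin])
  }, numeric(1))
  expect_true(all(deltas > 0))
})

test_that("raising a motif weight raises the planted component mean", {
  bin <- motifTriadIndex("C-RK-AGV")
  meanAt <- function(w) {
    mean(vapply(1:20, function(s) {
      x <- generateCollection(c(pos = 6L), lengthRange = c(80L, 120L),
                              motifs = list(pos = "C-RK-AGV"),
                              weights = list(pos = w), seed = s)
      mean(featureValues(computeCTF(sequences(x)))[, bin])
    }, numeric(1)))
  }
  m1 <- meanAt(1); m3 <- meanAt(3); m6 <- meanAt(6)
  expect_lt(m1, m3)
  expect_lt(m3, m6)
})

test_that("the default benchmark mirrors the real collection's shape", {
  x <- defaultBenchmark(seed = 4)
  lab <- as.character(classLabels(x))
  expect_equal(sum(lab != "non-NR"), 474L)
  expect_equal(sum(lab == "non-NR"), 500L)
  expect_equal(as.vector(table(factor(lab[lab != "non-NR"],
                                      paste0("NR", 1:8)))),
               c(162L, 140L, 82L, 23L, 29L, 7L, 21L, 10L))
  info <- collectionInfo(x)
  expect_length(info$discriminative, 4L)
  expect_length(info$subfamilyMotifs, 8L)
  # scaled replica keeps the proportions but shrinks the cost
  s <- defaultBenchmark(seed = 4, scale = 0.1)
  expect_equal(sum(as.character(classLabels(s)) == "non-NR"), 50L)
})

test_that("collections export to FASTA plus label file for the CLI", {
  x <- generateCollection(c(NR1 = 4L, "non-NR" = 4L),
                          lengthRange = c(30L, 50L), seed = 2)
  fa <- tempfile(fileext = ".fa"); lab <- tempfile(fileext = ".tsv")
  writeCollection(x, fa, lab)
  seqs <- readProteinFasta(fa)
  labels <- readLabels(lab, c("NR1", "non-NR"))
  expect_equal(names(seqs), names(sequences(x)))
  expect_equal(unname(labels[names(seqs)]),
               as.character(classLabels(x)))
})
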