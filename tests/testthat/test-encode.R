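test_that("AAC is the normalized residue frequency in alphabetical order", {
  v <- featureValues(computeAAC(c(s = "AAAA")))
  expect_equal(unname(v[1, "A"]), 1)
  expect_equal(sum(v), 1)

  u <- featureValues(computeAAC(c(s = "ACDEFGHIKLMNPQRSTVWY")))
  expect_equal(unname(u[1, ]), rep(0.05, 20))
  expect_equal(colnames(u), sort(AA))

  w <- featureValues(computeAAC(c(s = "MKV")))
  expect_equal(unname(w[1, c("K", "M", "V")]), rep(1 / 3, 3))
  expect_equal(sum(w[1, setdiff(colnames(w), c("K", "M", "V"))]), 0)

  expect_error(computeAAC(c(s = "")), "empty")
})

test_that("sequence reduction follows the seven-class partition", {
  expect_equal(reduceSequence("AGV"), c(1L, 1L, 1L))
  expect_equal(reduceSequence("C"), 7L)
  expect_equal(reduceSequence("RKDE"), c(5L, 5L, 6L, 6L))
  expect_error(reduceSequence("MKXV"), "position 3")
})

test_that("the triad index is the stated bijection over 1..343", {
  expect_equal(triadIndex(1, 1, 1), 1L)
  expect_equal(triadIndex(7, 7, 7), 343L)
  expect_equal(triadIndex(1, 7, 6), 48L)
  all343 <- triadIndex(rep(1:7, each = 49), rep(rep(1:7, each = 7), 7),
                       rep(1:7, 49))
  expect_equal(sort(all343), 1:343)
  expect_error(triadIndex(0, 1, 1), "1..7")
  expect_error(triadIndex(1, 8, 1), "1..7")
})

test_that("CTF counts sliding triads normalized by L - 2", {
  v <- featureValues(computeCTF(c(s = "AAA")))
  expect_equal(unname(v[1, triadIndex(1, 1, 1)]), 1)
  expect_equal(sum(v), 1)
  expect_equal(ncol(v), 343L)

  w <- featureValues(computeCTF(c(s = "ACDA")))
  expect_equal(unname(w[1, triadIndex(1, 7, 6)]), 0.5)
  expect_equal(unname(w[1, triadIndex(7, 6, 1)]), 0.5)

  expect_error(computeCTF(c(s = "MK")), "3")
})

test_that("CTF equals a naive 3-mer dictionary oracle on random sequences", {
  seqs <- randomSeqs(200, minLen = 3L, maxLen = 500L, seed = 42)
  got <- featureValues(computeCTF(seqs))
  for (i in seq_along(seqs)) {
    oracle <- ctfOracleCounts(seqs[[i]])
    expected <- numeric(343)
    for (key in names(oracle)) {
      cls <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
      expected[triadIndex(cls[1], cls[2], cls[3])] <- oracle[[key]]
    }
    expect_equal(unname(got[i, ]), expected, tolerance = 1e-12)
  }
})

test_that("every encoder block is a probability vector on random input", {
  seqs <- randomSeqs(40, minLen = 3L, maxLen = 200L, seed = 7)
  expect_equal(unname(rowSums(featureValues(computeAAC(seqs)))),
               rep(1, 40))
  expect_equal(unname(rowSums(featureValues(computeCTF(seqs)))),
               rep(1, 40))
  expect_equal(unname(rowSums(featureValues(computeCGR(seqs)))),
               rep(1, 40))
})

test_that("reordering residues changes CTF and CGR but never AAC", {
  set.seed(5)
  base <- sample(c(rep(AA, 3), sample(AA, 20, TRUE)))
  a <- paste(base, collapse = "")
  b <- paste(rev(base), collapse = "")
  expect_equal(featureValues(computeAAC(c(x = a)))[1, ],
               featureValues(computeAAC(c(x = b)))[1, ])
  expect_false(isTRUE(all.equal(
    featureValues(computeCTF(c(x = a)))[1, ],
    featureValues(computeCTF(c(x = b)))[1, ])))
  expect_false(isTRUE(all.equal(
    featureValues(computeCGR(c(x = a)))[1, ],
    featureValues(computeCGR(c(x = b)))[1, ])))
})

test_that("feature blocks concatenate to the documented dimensions", {
  seqs <- randomSeqs(3, minLen = 10L, maxLen = 20L, seed = 2)
  dims <- c("AAC" = 20L, "CGR" = 24L, "CTF" = 343L, "AAC+CGR" = 44L,
            "AAC+CTF" = 363L, "CTF+CGR" = 367L, "CTF+CGR+AAC" = 387L)
  for (fs in names(dims)) {
    pf <- computeFeatures(seqs, fs)
    expect_equal(ncol(featureValues(pf)), unname(dims[fs]))
    expect_equal(featureSet(pf), fs)
  }
  # canonical order is enforced regardless of user spelling
  expect_equal(featureSet(computeFeatures(seqs, "ctf+aac")), "AAC+CTF")
  # single block is returned unchanged
  aac <- computeAAC(seqs)
  expect_identical(combineFeatures(list(aac)), aac)
  expect_error(combineFeatures(list(aac, aac)), "distinct")
  expect_error(normalizeFeatureSet("aac+pse"), "unknown feature set")
})

test_that("motif strings map to their triad bins", {
  expect_equal(motifTriadIndex("C-RK-AGV"), triadIndex(7, 5, 1))
  expect_equal(motifTriadIndex("CKA"), triadIndex(7, 5, 1))
  expect_error(motifTriadIndex("C-RK"), "malformed")
})
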