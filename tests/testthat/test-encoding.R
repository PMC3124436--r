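test_that("spatial windows rank neighbours by Calpha distance", {
  # residues on a line at 0, 1, 3, 6, 10
  ch <- caOnlyChain(cbind(c(0, 1, 3, 6, 10), 0, 0))
  expect_equal(spatialWindow(ch, 1, M = 1L), 1L)
  expect_equal(spatialWindow(ch, 1, M = 3L), c(1L, 2L, 3L))
  # distances from residue 3: 2 (res 2), 3 (res 1 and 4, tie -> lower
  # index first), 7 (res 5)
  expect_equal(spatialWindow(ch, 3, M = 5L), c(3L, 2L, 1L, 4L, 5L))
  # chain shorter than M: window is the whole chain
  expect_equal(length(spatialWindow(ch, 1, M = 15L)), 5L)
  # symmetric tie: the lower residue index wins
  sym <- caOnlyChain(cbind(c(-1, 0, 1), 0, 0))
  expect_equal(spatialWindow(sym, 2, M = 2L), c(2L, 1L))
})

test_that("encoded vectors have the lengths their layout promises", {
  fx <- makeToyComplex(fixtureSpec(seed = 10))
  profile <- scalePssm(synthPssm(chainSequence(fx$chain), fx$truth, 8, 3))
  geom <- geometryFeatures(fx$chain)

  w <- spatialWindow(fx$chain, 5, M = 15L)
  full <- encodeStructure(w, profile, geom, M = 15L)
  expect_length(full, 495L)
  expect_true(all(full >= 0 & full <= 1))

  pssmOnly <- encodeStructure(w, profile, NULL, M = 15L, mask = "pssm")
  expect_length(pssmOnly, 300L)
  expect_equal(pssmOnly[1:20], as.numeric(profile[5, ]))

  sq <- encodeSequencePssm(profile, 30, N = 17L)
  expect_length(sq, 340L)
  bin <- encodeSequenceBinary(chainSequence(fx$chain), 30, N = 17L)
  expect_length(bin, 357L)
})

test_that("window members carry their features in ranked order", {
  fx <- makeToyComplex(fixtureSpec(seed = 10))
  profile <- scalePssm(synthPssm(chainSequence(fx$chain), fx$truth, 8, 3))
  geom <- geometryFeatures(fx$chain)
  w <- spatialWindow(fx$chain, 7, M = 4L)
  v <- encodeStructure(w, profile, geom, M = 4L)
  for (j in seq_along(w)) {
    block <- v[(j - 1) * 33 + seq_len(33)]
    expect_equal(block[1:20], as.numeric(profile[w[j], ]))
    expect_equal(block[21], geom$rasa[w[j]])
    expect_equal(block[22:27], as.numeric(geom[w[j], paste0("dpx", 1:6)]))
    expect_equal(block[28:33], as.numeric(geom[w[j], paste0("cx", 1:6)]))
  }
})

test_that("short windows and termini are zero-padded", {
  short <- caOnlyChain(cbind(c(0, 4, 8), 0, 0))
  profile <- matrix(0.7, 3, 20)
  geom <- as.data.frame(matrix(0.3, 3, 13))
  names(geom) <- c("rasa", paste0("dpx", 1:6), paste0("cx", 1:6))
  v <- encodeStructure(spatialWindow(short, 1, M = 15L), profile, geom, M = 15L)
  expect_length(v, 495L)
  expect_true(all(v[(3 * 33 + 1):495] == 0))

  # N-terminal target: first 8 sliding-window blocks are zeros
  sq <- encodeSequencePssm(matrix(0.7, 30, 20), 1, N = 17L)
  expect_true(all(sq[1:160] == 0))
  expect_true(all(sq[161:340] == 0.7))
})

test_that("binary patterns are exact one-hots with padding bits", {
  v <- encodeSequenceBinary("ACD", 1, N = 3L)
  expect_length(v, 63L)
  expect_equal(sum(v), 3)                       # exactly N set bits
  expect_equal(v[21], 1)                        # overhang -> padding bit
  expect_equal(which(v[22:42] == 1), 1L)        # "A" -> bit 1
  expect_equal(which(v[43:63] == 1),
               match("C", hemescan:::PSSM_ALPHABET))
  # X maps to the padding/unknown bit
  vx <- encodeSequenceBinary("AXD", 2, N = 1L)
  expect_equal(which(vx == 1), 21L)
})

test_that("even sliding windows are rejected", {
  expect_error(encodeSequencePssm(matrix(0.5, 9, 20), 5, N = 4L), "odd")
  expect_error(encodeSequenceBinary("ACDEF", 3, N = 2L), "odd")
})

test_that("chain encodings are complete, bounded and label residues scored", {
  fx <- makeToyComplex(fixtureSpec(seed = 12))
  profile <- scalePssm(synthPssm(chainSequence(fx$chain), fx$truth, 8, 3))
  geom <- geometryFeatures(fx$chain)
  X <- encodeChain(fx$chain, profile, geom, "structure")
  expect_equal(dim(X), c(60L, 495L))
  expect_true(all(attr(X, "scored")))
  expect_true(all(X >= 0 & X <= 1))
  Xs <- encodeChain(fx$chain, profile, layout = "seqPssm")
  expect_equal(dim(Xs), c(60L, 340L))
  expect_true(all(Xs >= 0 & Xs < 1))
})

test_that("LIBSVM export writes one sparse row per residue", {
  X <- rbind(c(0, 0.5, 0), c(0.25, 0, 1))
  f <- tempfile()
  writeLibsvm(X, c(1, 0), f)
  lines <- readLines(f)
  expect_equal(lines, c("1 2:0.5", "0 1:0.25 3:1"))
})
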