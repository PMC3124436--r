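test_that("isolated and well-separated atoms have closed-form SASA", {
  ch <- caOnlyChain(rbind(c(0, 0, 0)))
  s <- computeSasa(ch)
  expect_equal(s$perAtom, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)

  ch2 <- caOnlyChain(rbind(c(0, 0, 0), c(20, 0, 0)))
  s2 <- computeSasa(ch2)
  expect_equal(s2$perAtom, rep(4 * pi * (1.70 + 1.4)^2, 2), tolerance = 1e-6)
  expect_equal(s2$perResidue, s2$perAtom)
})

test_that("SASA agrees with an independent point-sampling oracle", {
  ch <- octahedralCage(d = 2.2)
  s <- computeSasa(ch)
  # tight cage: the central atom is fully occluded
  expect_lt(s$perAtom[1], 1e-6)
  oracle <- sasaOracle(ch)
  expect_equal(s$perAtom, oracle, tolerance = 0.02 * 4 * pi * 3.1^2 + 1e-9,
               ignore_attr = TRUE)
})

test_that("SASA quadrature converges when the lattice is refined", {
  fx <- makeToyComplex(fixtureSpec(seed = 5))
  s1 <- computeSasa(fx$chain, nPoints = 960L)
  s2 <- computeSasa(fx$chain, nPoints = 1920L)
  # total surface converges tightly ...
  expect_lt(abs(sum(s1$perResidue) - sum(s2$perResidue)) /
              sum(s2$perResidue), 0.005)
  # ... and on the scale the feature lives on (relative accessibility),
  # no residue moves by more than 2 points
  r1 <- computeRasa(fx$chain, s1)
  r2 <- computeRasa(fx$chain, s2)
  expect_lt(max(abs(r1 - r2)), 0.02)
})

test_that("RASA is the clamped ratio to the Rost-Sander maximum", {
  ch <- caOnlyChain(rbind(c(0, 0, 0)), aa = "G")
  s <- computeSasa(ch)
  expect_equal(computeRasa(ch, s), min(s$perResidue / 84, 1))
  # zero SASA -> 0; at or above the maximum -> clamped to 1
  expect_equal(computeRasa(ch, list(perResidue = 0)), 0, ignore_attr = TRUE)
  expect_equal(computeRasa(ch, list(perResidue = 84)), 1, ignore_attr = TRUE)
  expect_equal(computeRasa(ch, list(perResidue = 1.3 * 84)), 1,
               ignore_attr = TRUE)
})

test_that("depth matches the exhaustive brute-force scan on the cage", {
  ch <- octahedralCage(d = 2.2)
  s <- computeSasa(ch)
  at <- atomTable(ch)
  depth6 <- computeDpx(ch, s)
  oracle <- dpxOracle(ch, s)
  # per-residue = per-atom here (one atom per residue)
  expect_equal(unname(depth6[, 1]), oracle)
  # the buried centre is exactly the cage spacing away from accessibility
  expect_equal(unname(depth6[1, 1]), 2.2)
  # cage atoms are exposed: depth zero, all six statistics zero
  expect_true(all(depth6[-1, ] == 0))
})

test_that("fully exposed residues have all-zero depth statistics", {
  ch <- caOnlyChain(rbind(c(0, 0, 0)))
  s <- computeSasa(ch)
  expect_true(all(computeDpx(ch, s) == 0))
})

test_that("a chain with no accessible atoms is a geometry error", {
  ch <- caOnlyChain(rbind(c(0, 0, 0)))
  expect_error(computeDpx(ch, list(perAtom = 0)), "degenerate")
})

test_that("protrusion matches closed forms and the brute-force count", {
  vSphere <- 4 / 3 * pi * 1000
  one <- caOnlyChain(rbind(c(0, 0, 0)))
  expect_equal(unname(computeCx(one)[1, 1]), (vSphere - 20.1) / 20.1)

  two <- caOnlyChain(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(unname(computeCx(two)[, 1]),
               rep((vSphere - 40.2) / 40.2, 2))

  # dense cubic lattice filling the sphere: central atom CX below 1
  g <- as.matrix(expand.grid(x = seq(-9, 9, 1.8), y = seq(-9, 9, 1.8),
                             z = seq(-9, 9, 1.8)))
  g <- g[rowSums(g^2) <= 100, ]
  g <- rbind(c(0, 0, 0), g[rowSums(abs(g)) > 0, ])
  lat <- caOnlyChain(g)
  cx <- computeCx(lat)
  expect_lt(cx[1, 1], 1)
  expect_equal(unname(cx[, 1]), cxOracle(lat), tolerance = 1e-9)
})

test_that("logistic scaling matches closed-form values", {
  expect_equal(logisticScale(0), 0.5)
  expect_equal(logisticScale(1), 0.7311, tolerance = 1e-4)
  expect_equal(logisticScale(-3), 0.0474, tolerance = 1e-3)
  expect_equal(logisticScale(7), 0.9991, tolerance = 1e-4)
})

test_that("burial monotonicity: enclosing an atom never decreases depth", {
  base <- octahedralCage(d = 2.6)
  s <- computeSasa(base)
  d0 <- computeDpx(base, s)[1, 1]
  # add a second, tighter shell of atoms
  shell <- as.matrix(expand.grid(x = c(-4, 4), y = c(-4, 4), z = c(-4, 4)))
  at <- atomTable(base)
  aug <- rbind(at[, c("x", "y", "z")], as.data.frame(shell))
  ch2 <- caOnlyChain(as.matrix(aug))
  d1 <- computeDpx(ch2, computeSasa(ch2))[1, 1]
  expect_gte(d1, d0)
})

test_that("adding atoms inside the sphere never increases protrusion", {
  one <- caOnlyChain(rbind(c(0, 0, 0)))
  two <- caOnlyChain(rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_lt(computeCx(two)[1, 1], computeCx(one)[1, 1])
})

test_that("all scaled geometry features lie in [0, 1] on fixtures", {
  for (s in c(3, 11)) {
    fx <- makeToyComplex(fixtureSpec(seed = s))
    g <- geometryFeatures(fx$chain)
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(g[, -1] > 0 & g[, -1] < 1))  # logistic-scaled blocks
  }
})
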