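test_that("contact labelling respects the distance cutoff boundary", {
  # two single-atom residues at 4.4 and 6.0 A from a one-atom heme
  ch <- caOnlyChain(rbind(c(4.4, 0, 0), c(6.0, 0, 0)))
  heme <- hemeFromXyz(rbind(c(0, 0, 0)))
  lab <- labelBindingResidues(ch, list(heme), cutoff = 4.5)
  expect_equal(bindingLabels(lab), c(1L, 0L))
})

test_that("labels are monotone in the cutoff", {
  fx <- makeToyComplex(fixtureSpec(seed = 9))
  l1 <- bindingLabels(labelBindingResidues(fx$chain, fx$hemes, 4.0))
  l2 <- bindingLabels(labelBindingResidues(fx$chain, fx$hemes, 4.5))
  l3 <- bindingLabels(labelBindingResidues(fx$chain, fx$hemes, 6.0))
  expect_true(all(l2 >= l1))
  expect_true(all(l3 >= l2))
})

test_that("multi-heme labels are the union of single-heme label sets", {
  fx <- makeToyComplex(fixtureSpec(hemesPerChain = 2, seed = 6))
  both <- bindingLabels(labelBindingResidues(fx$chain, fx$hemes))
  one <- bindingLabels(labelBindingResidues(fx$chain, fx$hemes[1]))
  two <- bindingLabels(labelBindingResidues(fx$chain, fx$hemes[2]))
  expect_equal(both, as.integer(one | two))
  # brute-force distance scan agrees
  at <- atomTable(fx$chain)
  hx <- do.call(rbind, lapply(fx$hemes, function(h)
    as.matrix(atomTable(h)[, c("x", "y", "z")])))
  manual <- vapply(seq_len(nResidues(fx$chain)), function(i) {
    a <- as.matrix(at[at$residue == i, c("x", "y", "z")])
    dmin <- min(vapply(seq_len(nrow(a)), function(r)
      min(sqrt((hx[, 1] - a[r, 1])^2 + (hx[, 2] - a[r, 2])^2 +
               (hx[, 3] - a[r, 3])^2)), 0))
    as.integer(dmin <= 4.5)
  }, integer(1))
  expect_equal(both, manual)
})

test_that("an empty heme list labels everything non-binding with a warning", {
  fx <- makeToyComplex(fixtureSpec(seed = 2))
  expect_warning(lab <- labelBindingResidues(fx$chain, list()), "no heme")
  expect_equal(sum(bindingLabels(lab)), 0)
})

test_that("interface propensity matches closed forms", {
  # identical composition in interface and rest -> all defined ratios 0
  ch <- caOnlyChain(matrix(seq_len(8) * 10, 8, 3), aa = rep(c("A", "C"), 4))
  lab <- methods::new("LabeledChain", chain = ch,
                      labels = c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L))
  pt <- interfacePropensity(list(lab))
  expect_equal(pt$log2Ratio[pt$aa %in% c("A", "C")], c(0, 0))
  expect_true(all(pt$undefined[!pt$aa %in% c("A", "C")]))

  # 10% interface vs 5% background -> log2(2) = +1
  aa <- c(rep("C", 1), rep("A", 9),        # interface: 10% C
          rep("C", 1), rep("A", 19))       # rest: 5% C
  ch2 <- caOnlyChain(matrix(seq_along(aa) * 10, length(aa), 3), aa = aa)
  lab2 <- methods::new("LabeledChain", chain = ch2,
                       labels = c(rep(1L, 10), rep(0L, 20)))
  pt2 <- interfacePropensity(list(lab2))
  expect_equal(pt2$log2Ratio[pt2$aa == "C"], 1)
})

test_that("planted patches are enriched in Cys/His/Met/Phe", {
  samples <- lapply(1:6, function(s) makeToyComplex(fixtureSpec(seed = s)))
  labs <- lapply(samples, function(fx)
    methods::new("LabeledChain", chain = fx$chain, labels = fx$truth))
  pt <- interfacePropensity(labs)
  expect_gt(pt$log2Ratio[pt$aa == "C"], 0)
  expect_gt(pt$log2Ratio[pt$aa == "H"], 0)
  # the interface class as a whole is enriched in the four types
  chmf <- pt$log2Ratio[pt$aa %in% c("C", "H", "M", "F")]
  expect_gt(mean(chmf, na.rm = TRUE), 0)
})

test_that("neighbour binding counts match an exhaustive scan", {
  fx <- makeToyComplex(fixtureSpec(seed = 8))
  k <- 18L
  counts <- neighborBindingCount(fx$chain, fx$truth, k)
  # brute force: full distance matrix over Calphas
  at <- atomTable(fx$chain)
  ca <- as.matrix(at[at$atomName == "CA", c("x", "y", "z")])
  n <- nrow(ca)
  manual <- vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums((ca - matrix(ca[i, ], n, 3, byrow = TRUE))^2))
    ord <- order(d, seq_len(n))
    nb <- setdiff(ord, i)[seq_len(k)]
    sum(fx$truth[nb])
  }, integer(1))
  expect_equal(counts, manual)
  # clustering: binding residues see more binding neighbours
  expect_gt(mean(counts[fx$truth == 1]), mean(counts[fx$truth == 0]))

  # degenerate cases
  expect_equal(neighborBindingCount(fx$chain, rep(0L, 60), k),
               rep(0L, 60))
  # a lone binding residue: its own count is 0 (neighbours only), and a
  # residue counts 1 exactly when the lone residue is among its k nearest
  # (k-NN graphs are directed, so that need not be k residues)
  lone <- c(1L, rep(0L, 59))
  cl <- neighborBindingCount(fx$chain, lone, k)
  expect_equal(cl[1], 0L)
  pointsAt1 <- vapply(seq_len(n), function(i) {
    if (i == 1) return(FALSE)
    d <- sqrt(rowSums((ca - matrix(ca[i, ], n, 3, byrow = TRUE))^2))
    1 %in% setdiff(order(d, seq_len(n)), i)[seq_len(k)]
  }, logical(1))
  expect_equal(cl == 1L, pointsAt1)
})

test_that("the KS comparison behaves as the standard two-sample test", {
  x <- rnorm(50)
  same <- attributeDistributionTest(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  disjoint <- attributeDistributionTest(1:50, 101:150)
  expect_equal(disjoint$statistic, 1)

  set.seed(123)
  a <- rnorm(200); b <- rnorm(200, mean = 1)
  shifted <- attributeDistributionTest(a, b)
  expect_lt(shifted$p.value, 0.01)
  ref <- suppressWarnings(stats::ks.test(a, b))
  expect_equal(shifted$statistic, unname(ref$statistic))
})
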