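test_that("balanced sampling draws all positives and matching negatives", {
  labels <- c(rep(1L, 10), rep(0L, 100))
  idx <- balancedSample(labels, seed = 3)
  expect_length(idx, 20)
  expect_equal(sum(labels[idx] == 1), 10)
  expect_equal(sum(labels[idx] == 0), 10)
  # determinism per seed
  expect_identical(idx, balancedSample(labels, seed = 3))
  expect_false(identical(idx, balancedSample(labels, seed = 4)))
  # boundary: already balanced -> the whole set
  expect_identical(balancedSample(rep(c(1L, 0L), 10), seed = 1), 1:20)
  expect_error(balancedSample(c(1L, 1L, 0L)), "cannot balance")
})

test_that("grid search separates a separable toy problem", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, mean = 0), ncol = 2),
             matrix(rnorm(60, mean = 4), ncol = 2))
  y <- rep(c(0L, 1L), each = 30)
  fit <- gridSearchTrain(X, y, cGrid = c(1, 10), gammaGrid = c(0.1, 1),
                         seed = 1)
  expect_equal(.subset2(fit, "cvMcc") > 0.9, TRUE)
  pred <- as.integer(as.character(predict(fit$model, X)))
  expect_equal(pred, y)
  expect_error(gridSearchTrain(X, rep(1L, 60)), "single class")
})

test_that("label-shuffled training yields near-zero internal CV MCC", {
  set.seed(10)
  X <- matrix(runif(120 * 10), 120, 10)
  mccs <- vapply(1:10, function(r) {
    set.seed(100 + r)
    y <- sample(rep(c(0L, 1L), 60))
    fit <- gridSearchTrain(X, y, cGrid = 1, gammaGrid = 0.1, seed = r)
    fit$cvMcc
  }, 0)
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("fold plans partition chains evenly", {
  f <- foldPlan(23, nFolds = 5, seed = 2)
  expect_length(f, 23)
  expect_true(all(diff(range(table(f))) <= 1))
  expect_identical(f, foldPlan(23, nFolds = 5, seed = 2))
  expect_error(foldPlan(4, nFolds = 5), "at least 5")
})

test_that("prediction tracks respect scored markers and layouts", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 4), ncol = 2))
  y <- rep(c(0L, 1L), each = 20)
  fit <- gridSearchTrain(X, y, cGrid = 1, gammaGrid = 0.5, seed = 1)

  Xnew <- X[1:6, ]
  attr(Xnew, "scored") <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  track <- predictChain(fit, Xnew)
  expect_equal(is.na(track), !attr(Xnew, "scored"))
  # determinism: identical input vectors give identical calls
  expect_identical(track, predictChain(fit, Xnew))
  # layout mismatch is an error
  expect_error(predictChain(fit, matrix(0.5, 3, 7)), "layout mismatch")
})

test_that("chain-level cross-validation tests every chain exactly once", {
  set.seed(21)
  samples <- lapply(1:5, function(s) makeToyComplex(fixtureSpec(seed = 20 + s)))
  labeled <- lapply(samples, function(fx)
    methods::new("LabeledChain", chain = fx$chain, labels = fx$truth))
  Xs <- lapply(samples, function(fx) {
    profile <- scalePssm(synthPssm(chainSequence(fx$chain), fx$truth, 8,
                                   seed = sum(fx$truth)))
    encodeChain(fx$chain, profile, layout = "seqPssm")
  })
  cv <- cvTracks(Xs, labeled, nFolds = 5, seed = 1,
                 cGrid = c(1, 10), gammaGrid = c(0.01, 0.1))
  expect_equal(sort(cv$fold), 1:5)              # one chain per fold
  expect_true(all(!vapply(cv$tracks, is.null, TRUE)))
  expect_true(all(vapply(cv$tracks, length, 0L) == 60))

  # leakage guard: duplicated chain objects are rejected
  expect_error(cvTracks(Xs[c(1, 1, 2, 3, 4)], labeled[c(1, 1, 2, 3, 4)],
                        nFolds = 5, seed = 1),
               "duplicated chains")
})

test_that("a model recalls its own balanced training set on fixtures", {
  fx <- makeToyComplex(fixtureSpec(seed = 30))
  profile <- scalePssm(synthPssm(chainSequence(fx$chain), fx$truth, 8, 7))
  X <- encodeChain(fx$chain, profile, layout = "seqPssm")
  idx <- balancedSample(fx$truth, seed = 2)
  fit <- gridSearchTrain(X[idx, ], fx$truth[idx], cGrid = c(1, 10),
                         gammaGrid = c(0.01, 0.1), seed = 1)
  pred <- as.integer(as.character(predict(fit$model, X[idx, ])))
  cc <- confusionCounts(pred, fx$truth[idx])
  expect_gte(computeMetrics(cc)[["recall"]], 50)
})
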