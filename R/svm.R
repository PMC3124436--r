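## RBF-SVM training and chain-level cross-validation machinery.
## Training sets are always class-balanced (all positives plus an equal
## number of randomly drawn negatives); hyper-parameters come from an
## exhaustive grid search scored by internal 5-fold cross-validated MCC;
## cross-validation folds split by protein chain, never by residue, so a
## chain's residues are never divided between training and testing.

#' Canonical hyper-parameter grids
#'
#' The standard LIBSVM coarse grid: `C` in `2^-5 .. 2^15` and `gamma` in
#' `2^-15 .. 2^3`, both in steps of `x4`.
#'
#' @return list with `cGrid` and `gammaGrid`.
#' @export
defaultGrids <- function() {
  list(cGrid = 2^seq(-5, 15, by = 2), gammaGrid = 2^seq(-15, 3, by = 2))
}

#' Balanced training sample
#'
#' All positives plus an equal number of negatives drawn without
#' replacement, reproducibly for a given seed.
#'
#' @param labels 0/1 integer vector (`NA` allowed; never sampled).
#' @param seed integer seed for the negative draw.
#' @return sorted integer indices into `labels`.
#' @export
balancedSample <- function(labels, seed = 1L) {
  pos <- which(!is.na(labels) & labels == 1L)
  neg <- which(!is.na(labels) & labels == 0L)
  if (length(neg) < length(pos))
    stop("fewer non-binding than binding residues; cannot balance",
         call. = FALSE)
  set.seed(seed)
  negPick <- neg[sample.int(length(neg), length(pos))]
  sort(c(pos, negPick))
}

.mccOf <- function(pred, truth) {
  unname(computeMetrics(confusionCounts(pred, truth))["mcc"])
}

.fitSvm <- function(X, y, C, gamma) {
  e1071::svm(x = X, y = factor(y, levels = c(0, 1)), type = "C-classification",
             kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
}

.svmPredict <- function(model, X) {
  as.integer(as.character(predict(model, X)))
}

#' Grid-search training of one RBF-SVM
#'
#' Evaluates every `(C, gamma)` pair of the grid by internal k-fold
#' cross-validated MCC on the supplied (balanced) training set, breaks
#' ties toward smaller `C` then smaller `gamma`, and refits the winning
#' pair on all supplied data.
#'
#' @param X numeric feature matrix (rows = residues).
#' @param y 0/1 labels.
#' @param cGrid,gammaGrid candidate values (defaults: [defaultGrids()]).
#' @param nFolds internal folds (default 5).
#' @param seed seed for the internal fold shuffle.
#' @return list with `model` (an `e1071::svm` fit), `C`, `gamma`,
#'   `cvMcc` (internal-CV MCC of the chosen pair).
#' @export
gridSearchTrain <- function(X, y, cGrid = defaultGrids()$cGrid,
                            gammaGrid = defaultGrids()$gammaGrid,
                            nFolds = 5L, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep(seq_len(nFolds), length.out = n))
  ## guard: every internal training split must keep both classes
  for (f in seq_len(nFolds))
    if (length(unique(y[fold != f])) < 2L)
      fold <- (seq_len(n) + f) %% nFolds + 1L
  best <- list(mcc = -Inf, C = NA_real_, gamma = NA_real_)
  for (C in sort(cGrid)) {
    for (g in sort(gammaGrid)) {
      pred <- integer(n)
      for (f in seq_len(nFolds)) {
        te <- fold == f
        m <- .fitSvm(X[!te, , drop = FALSE], y[!te], C, g)
        pred[te] <- .svmPredict(m, X[te, , drop = FALSE])
      }
      mcc <- .mccOf(pred, y)
      if (mcc > best$mcc + 1e-12) best <- list(mcc = mcc, C = C, gamma = g)
    }
  }
  list(model = .fitSvm(X, y, best$C, best$gamma),
       C = best$C, gamma = best$gamma, cvMcc = best$mcc)
}

#' Chain-level fold plan
#'
#' @param nChains number of chains.
#' @param nFolds number of folds (default 5).
#' @param seed shuffle seed.
#' @return integer fold assignment per chain; fold sizes differ by at
#'   most one chain.
#' @export
foldPlan <- function(nChains, nFolds = 5L, seed = 1L) {
  if (nChains < nFolds)
    stop("need at least ", nFolds, " chains for ", nFolds, "-fold ",
         "cross-validation", call. = FALSE)
  set.seed(seed)
  sample(rep(seq_len(nFolds), length.out = nChains))
}

#' Predict every residue of one encoded chain
#'
#' @param model list as returned by [gridSearchTrain()], or a bare
#'   `e1071::svm` fit.
#' @param X encoded chain matrix from [encodeChain()] (its `"scored"`
#'   attribute marks residues that can be called).
#' @return integer track: 1/0 calls, `NA` for residues that were not
#'   scored.
#' @export
predictChain <- function(model, X) {
  if (is.list(model) && !is.null(model$model)) model <- model$model
  scored <- attr(X, "scored")
  if (is.null(scored)) scored <- rep(TRUE, nrow(X))
  track <- rep(NA_integer_, nrow(X))
  if (any(scored)) {
    Xs <- X[scored, , drop = FALSE]
    if (ncol(Xs) != ncol(model$SV))
      stop("feature layout mismatch between model and chain encoding",
           call. = FALSE)
    track[scored] <- .svmPredict(model, Xs)
  }
  track
}

## stable identity of a chain, used to reject duplicated chains that
## would leak between folds
.chainFingerprint <- function(labeled) {
  chain <- chainModel(labeled)
  xyz <- as.matrix(atomTable(chain)[, c("x", "y", "z")])
  paste(chainId(chain), chainSequence(chain),
        format(sum(xyz) + sum(xyz^2), digits = 15), sep = "|")
}

#' Cross-validated prediction tracks for one classifier path
#'
#' Splits chains into folds, and per fold draws a balanced sample from
#' the training chains' residues, grid-search-trains an SVM and predicts
#' every residue of the held-out chains.
#'
#' @param Xs list of encoded chain matrices (one per chain, same layout).
#' @param labeledChains list of [LabeledChain-class], aligned with `Xs`.
#' @param nFolds folds (default 5).
#' @param seed master seed; fold plan, per-fold negative sampling and
#'   grid-search shuffles all derive from it.
#' @param cGrid,gammaGrid hyper-parameter grids.
#' @return list with `tracks` (per-chain integer prediction tracks),
#'   `fold` (fold id per chain), `models` (per-fold `gridSearchTrain()`
#'   results).
#' @export
cvTracks <- function(Xs, labeledChains, nFolds = 5L, seed = 1L,
                     cGrid = defaultGrids()$cGrid,
                     gammaGrid = defaultGrids()$gammaGrid) {
  stopifnot(length(Xs) == length(labeledChains))
  fp <- vapply(labeledChains, .chainFingerprint, "")
  if (anyDuplicated(fp))
    stop("duplicated chains in the dataset would leak across folds",
         call. = FALSE)
  nC <- length(Xs)
  fold <- foldPlan(nC, nFolds, seed)
  ys <- lapply(seq_len(nC), function(i) {
    y <- bindingLabels(labeledChains[[i]])
    y[!attr(Xs[[i]], "scored")] <- NA_integer_
    y
  })
  tracks <- vector("list", nC)
  models <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    tr <- which(fold != f)
    Xtr <- do.call(rbind, Xs[tr])
    ytr <- unlist(ys[tr])
    keep <- !is.na(ytr)
    Xtr <- Xtr[keep, , drop = FALSE]; ytr <- ytr[keep]
    idx <- balancedSample(ytr, seed = seed * 1000L + f)
    stopifnot(sum(ytr[idx] == 1L) == sum(ytr[idx] == 0L))
    models[[f]] <- gridSearchTrain(Xtr[idx, , drop = FALSE], ytr[idx],
                                   cGrid, gammaGrid, seed = seed * 100L + f)
    for (i in which(fold == f))
      tracks[[i]] <- predictChain(models[[f]], Xs[[i]])
  }
  list(tracks = tracks, fold = fold, models = models)
}
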