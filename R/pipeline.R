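## End-to-end orchestration of the five prediction variants:
##   STR          structure path (spatial window, four-feature block)
##   STR_RFP      structure path + spatial false-positive filter
##   SEQ          sequence path (sliding window over the scaled profile)
##   STR+SEQ      AND vote of raw structure path and sequence path
##   STR_RFP+SEQ  AND vote of filtered structure path and sequence path
## Both SVM paths share one chain-level fold plan so their tracks are
## comparable residue-by-residue.

VARIANTS <- c("STR", "STR_RFP", "SEQ", "STR+SEQ", "STR_RFP+SEQ")

#' Default pipeline configuration
#'
#' Every constant of the method in one place: window sizes `M = 15` and
#' `N = 17`, filter parameters `W = 18` / `T = 5`, contact cutoff 4.5 A,
#' probe radius 1.4 A, protrusion sphere 10 A with 20.1 A^3 mean atom
#' volume, the canonical LIBSVM hyper-parameter grids, 5 folds.
#'
#' @param seed master seed; all stochastic stages (fold plan, negative
#'   sampling, grid-search shuffles) derive their streams from it.
#' @param ... named overrides of any listed constant.
#' @return configuration list.
#' @export
defaultConfig <- function(seed = 1L, ...) {
  cfg <- list(M = 15L, N = 17L, W = 18L, T = 5L,
              mask = FEATURE_NAMES,
              cutoff = 4.5, probeRadius = 1.4, nPoints = 960L,
              sphereRadius = 10, meanAtomVolume = 20.1,
              cGrid = defaultGrids()$cGrid,
              gammaGrid = defaultGrids()$gammaGrid,
              nFolds = 5L, seed = as.integer(seed))
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Per-chain feature preparation
#'
#' Computes the scaled profile and geometry block of each sample once.
#' All scalings are fixed closed forms (logistic, Rost-Sander maxima),
#' so no statistic is pooled across chains or folds.
#'
#' @param samples list of sample lists (`chain`, `truth`, `pssm`, and
#'   optionally `hemes`, `id`), e.g. from [makeBenchmark()] or
#'   [loadBenchmark()].
#' @param config a [defaultConfig()] list.
#' @param needGeometry compute the geometry block (skippable for
#'   sequence-only work).
#' @return the samples with `labeled` ([LabeledChain-class]), `profile`
#'   and `geometry` fields added.
#' @export
prepareSamples <- function(samples, config = defaultConfig(),
                           needGeometry = TRUE) {
  lapply(samples, function(s) {
    stopifnot(is(s$chain, "ChainModel"))
    s$labeled <- new("LabeledChain", chain = s$chain,
                     labels = as.integer(s$truth))
    s$profile <- if (!is.null(s$pssm)) scalePssm(s$pssm) else NULL
    if (needGeometry)
      s$geometry <- geometryFeatures(s$chain, config$probeRadius,
                                     config$nPoints, config$sphereRadius,
                                     config$meanAtomVolume)
    s
  })
}

.foldMetrics <- function(tracks, truths, fold) {
  perFold <- lapply(sort(unique(fold)), function(f) {
    i <- which(fold == f)
    computeMetrics(confusionCounts(unlist(tracks[i]), unlist(truths[i])))
  })
  list(perFold = perFold, mean = foldAverage(perFold),
       pooled = computeMetrics(confusionCounts(unlist(tracks),
                                               unlist(truths))))
}

#' Cross-validated run of the prediction variants
#'
#' Runs chain-level k-fold cross-validation of the structure and/or
#' sequence SVM paths (one shared fold plan), applies the false-positive
#' filter and the AND vote, and reports per-fold, fold-averaged and
#' pooled metrics for every requested variant.
#'
#' @param samples prepared samples ([prepareSamples()]; unprepared
#'   samples are prepared on the fly).
#' @param config a [defaultConfig()] list.
#' @param variants subset of
#'   `c("STR", "STR_RFP", "SEQ", "STR+SEQ", "STR_RFP+SEQ")`.
#' @return list with `fold` (fold id per chain), `truth` (per-chain label
#'   vectors), `tracks` (per variant, per chain) and `metrics` (per
#'   variant: `perFold`, `mean`, `pooled`).
#' @export
runCrossValidation <- function(samples, config = defaultConfig(),
                               variants = VARIANTS) {
  stopifnot(all(variants %in% VARIANTS))
  needStr <- any(variants != "SEQ")
  needSeq <- any(variants %in% c("SEQ", "STR+SEQ", "STR_RFP+SEQ"))
  needFilter <- any(variants %in% c("STR_RFP", "STR_RFP+SEQ"))
  if (is.null(samples[[1]]$labeled) ||
      (needStr && is.null(samples[[1]]$geometry)))
    samples <- prepareSamples(samples, config, needGeometry = needStr)
  usesPssm <- needSeq || ("pssm" %in% config$mask && needStr)
  if (usesPssm && any(vapply(samples, function(s) is.null(s$profile), TRUE)))
    stop("a PSSM-dependent variant was requested but PSSMs are missing",
         call. = FALSE)

  labeled <- lapply(samples, `[[`, "labeled")
  truth <- lapply(labeled, bindingLabels)
  chains <- lapply(samples, `[[`, "chain")

  strCv <- seqCv <- NULL
  if (needStr) {
    Xs <- lapply(samples, function(s)
      encodeChain(s$chain, s$profile, s$geometry, "structure",
                  M = config$M, mask = config$mask))
    strCv <- cvTracks(Xs, labeled, config$nFolds, config$seed,
                      config$cGrid, config$gammaGrid)
  }
  if (needSeq) {
    Xs <- lapply(samples, function(s)
      encodeChain(s$chain, s$profile, layout = "seqPssm", N = config$N))
    seqCv <- cvTracks(Xs, labeled, config$nFolds, config$seed,
                      config$cGrid, config$gammaGrid)
  }
  fold <- if (needStr) strCv$fold else seqCv$fold

  trackSets <- list()
  if (needStr) trackSets[["STR"]] <- strCv$tracks
  if (needFilter)
    trackSets[["STR_RFP"]] <- lapply(seq_along(chains), function(i)
      filterFalsePositives(strCv$tracks[[i]], chains[[i]],
                           config$W, config$T))
  if (needSeq) trackSets[["SEQ"]] <- seqCv$tracks
  if ("STR+SEQ" %in% variants)
    trackSets[["STR+SEQ"]] <- lapply(seq_along(chains), function(i)
      voteCombine(strCv$tracks[[i]], seqCv$tracks[[i]]))
  if ("STR_RFP+SEQ" %in% variants)
    trackSets[["STR_RFP+SEQ"]] <- lapply(seq_along(chains), function(i)
      voteCombine(trackSets[["STR_RFP"]][[i]], seqCv$tracks[[i]]))

  metrics <- lapply(trackSets[intersect(VARIANTS, variants)],
                    .foldMetrics, truths = truth, fold = fold)
  list(fold = fold, truth = truth,
       tracks = trackSets[intersect(VARIANTS, names(trackSets))],
       metrics = metrics)
}

#' Run a single prediction variant
#'
#' @param samples,config as in [runCrossValidation()].
#' @param variant one of
#'   `c("STR", "STR_RFP", "SEQ", "STR+SEQ", "STR_RFP+SEQ")`.
#' @return list with `metrics` (`perFold`, `mean`, `pooled`) and `tracks`
#'   for the chosen variant, plus the `fold` plan.
#' @export
runVariant <- function(samples, variant = "STR_RFP+SEQ",
                       config = defaultConfig()) {
  variant <- match.arg(variant, VARIANTS)
  run <- runCrossValidation(samples, config, variants = variant)
  list(metrics = run$metrics[[variant]], tracks = run$tracks[[variant]],
       fold = run$fold)
}

#' Train final models on a whole dataset
#'
#' Trains the structure-path and sequence-path SVMs on all supplied
#' chains (balanced sampling, grid search) for later prediction on new
#' structures.
#'
#' @param samples,config as in [runCrossValidation()].
#' @return list with `strModel`, `seqModel` and the `config` used.
#' @export
trainModels <- function(samples, config = defaultConfig()) {
  samples <- prepareSamples(samples, config)
  labeled <- lapply(samples, `[[`, "labeled")
  fit <- function(layout) {
    Xs <- lapply(samples, function(s)
      if (layout == "structure")
        encodeChain(s$chain, s$profile, s$geometry, "structure",
                    M = config$M, mask = config$mask)
      else encodeChain(s$chain, s$profile, layout = "seqPssm", N = config$N))
    X <- do.call(rbind, Xs)
    y <- unlist(lapply(seq_along(Xs), function(i) {
      yy <- bindingLabels(labeled[[i]])
      yy[!attr(Xs[[i]], "scored")] <- NA_integer_
      yy
    }))
    keep <- !is.na(y)
    idx <- balancedSample(y[keep], seed = config$seed)
    gridSearchTrain(X[keep, , drop = FALSE][idx, , drop = FALSE],
                    y[keep][idx], config$cGrid, config$gammaGrid,
                    seed = config$seed)
  }
  list(strModel = fit("structure"), seqModel = fit("seqPssm"),
       config = config)
}

#' Predict heme-binding residues of one new structure
#'
#' Applies trained models ([trainModels()]) to a chain: structure path,
#' false-positive filter, sequence path, AND vote.
#'
#' @param models result of [trainModels()].
#' @param chain a [ChainModel-class].
#' @param pssm matching [PssmMatrix-class].
#' @return `data.frame` with one row per residue: position, amino acid
#'   and the five per-variant calls.
#' @export
predictStructure <- function(models, chain, pssm) {
  config <- models$config
  if (nchar(pssmSequence(pssm)) != nResidues(chain))
    stop("PSSM length does not match the chain", call. = FALSE)
  profile <- scalePssm(pssm)
  geometry <- geometryFeatures(chain, config$probeRadius, config$nPoints,
                               config$sphereRadius, config$meanAtomVolume)
  strX <- encodeChain(chain, profile, geometry, "structure",
                      M = config$M, mask = config$mask)
  seqX <- encodeChain(chain, profile, layout = "seqPssm", N = config$N)
  str <- predictChain(models$strModel, strX)
  strF <- filterFalsePositives(str, chain, config$W, config$T)
  seq <- predictChain(models$seqModel, seqX)
  res <- residueTable(chain)
  data.frame(position = res$resKey, aa = res$aa,
             STR = str, STR_RFP = strF, SEQ = seq,
             `STR+SEQ` = voteCombine(str, seq),
             `STR_RFP+SEQ` = voteCombine(strF, seq),
             check.names = FALSE)
}
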