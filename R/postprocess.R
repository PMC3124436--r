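## Post-processing of structure-path predictions: a single-pass spatial
## false-positive filter, and the hard-label AND vote that combines the
## (filtered) structure path with the sequence path.

#' Spatial false-positive reduction filter
#'
#' A residue predicted positive is reassigned negative when fewer than
#' `T` of its `W` nearest spatial neighbours (Calpha distance, target
#' excluded) are positive in the *raw* track.  The pass is applied
#' exactly once - neighbour counts always refer to the unfiltered input,
#' never to already-reassigned calls - and negatives are never flipped
#' to positive.
#'
#' @param track integer prediction track (1/0/NA).
#' @param chain the [ChainModel-class] the track belongs to.
#' @param W neighbourhood size (default 18); clamped with a warning when
#'   the chain has fewer than `W + 1` residues with a Calpha.
#' @param T minimum positive neighbours (default 5); must satisfy
#'   `1 <= T <= W`.
#' @return filtered integer track of the same length.
#' @export
filterFalsePositives <- function(track, chain, W = 18L, T = 5L) {
  stopifnot(is(chain, "ChainModel"), length(track) == nResidues(chain),
            T >= 1L, T <= W)
  nCa <- sum(residueTable(chain)$hasCa)
  if (nCa < W + 1L) {
    W <- nCa - 1L
    warning("chain smaller than W+1 residues; W clamped to ", W)
    T <- min(T, W)
  }
  nb <- .caNeighbours(chain, W)
  out <- track
  for (i in which(!is.na(track) & track == 1L)) {
    idx <- nb[[i]]
    if (is.null(idx)) next
    if (sum(!is.na(track[idx]) & track[idx] == 1L) < T) out[i] <- 0L
  }
  out
}

#' Voting combination of structure and sequence tracks
#'
#' A residue is called positive iff both input tracks call it positive
#' (logical AND on hard labels).  Residues unscored (`NA`) in either
#' track stay unscored.
#'
#' @param strTrack,seqTrack integer tracks of equal length.
#' @return combined integer track.
#' @export
voteCombine <- function(strTrack, seqTrack) {
  if (length(strTrack) != length(seqTrack))
    stop("tracks cover different residue sets", call. = FALSE)
  out <- as.integer(strTrack == 1L & seqTrack == 1L)
  out[is.na(strTrack) | is.na(seqTrack)] <- NA_integer_
  out
}

#' Filter parameter sweep
#'
#' Evaluates the false-positive filter over a grid of `W` values,
#' reporting for each `W` the `T` (searched from 1 to `W`) with the best
#' fold-averaged MCC.
#'
#' @param tracks list of raw structure-path tracks (one per chain).
#' @param labeledChains list of [LabeledChain-class] aligned with `tracks`.
#' @param fold fold id per chain (metrics are averaged over folds).
#' @param Wgrid neighbourhood sizes to try.
#' @return `data.frame` with one row per `W`: chosen `T` and the five
#'   fold-averaged measures.
#' @export
sweepFilterParams <- function(tracks, labeledChains, fold,
                              Wgrid = c(6L, 10L, 14L, 18L, 22L)) {
  truth <- lapply(labeledChains, bindingLabels)
  chains <- lapply(labeledChains, chainModel)
  rows <- lapply(Wgrid, function(W) {
    best <- NULL
    for (T in seq_len(W)) {
      filt <- lapply(seq_along(tracks), function(i)
        filterFalsePositives(tracks[[i]], chains[[i]], W, T))
      perFold <- lapply(sort(unique(fold)), function(f) {
        i <- which(fold == f)
        computeMetrics(confusionCounts(unlist(filt[i]), unlist(truth[i])))
      })
      m <- foldAverage(perFold)
      if (is.null(best) || m["mcc"] > best$m["mcc"] + 1e-12)
        best <- list(T = T, m = m)
    }
    c(W = W, T = best$T, best$m)
  })
  as.data.frame(do.call(rbind, rows))
}
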