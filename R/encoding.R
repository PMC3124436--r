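## Per-residue SVM input vectors.
##
## Structure path: a spatial window of M residues (the target plus its
## M-1 nearest neighbours by Calpha-Calpha distance, target first, ties
## to the smaller sequence index); each member contributes a 33-number
## block [20 scaled PSSM | 1 RASA | 6 scaled DPX | 6 scaled CX], subsets
## selectable through a feature mask; short windows are zero-padded.
##
## Sequence path: a sliding window of N consecutive positions centred on
## the target; either 20 scaled PSSM values per position or a 21-bit
## one-hot amino-acid pattern (20 types + 1 terminus/unknown bit).
## Positions beyond the termini are zero blocks (PSSM) or the padding bit.

FEATURE_NAMES <- c("pssm", "rasa", "dpx", "cx")
.FEATURE_WIDTH <- c(pssm = 20L, rasa = 1L, dpx = 6L, cx = 6L)

#' Spatial window of a residue
#'
#' @param chain a [ChainModel-class].
#' @param target 1-based residue index; must have a Calpha.
#' @param M window size (default 15).  If fewer than `M` residues carry a
#'   Calpha the window is the whole eligible chain.
#' @return integer vector of residue indices: the target first, then
#'   neighbours by increasing Calpha distance.
#' @export
spatialWindow <- function(chain, target, M = 15L) {
  stopifnot(is(chain, "ChainModel"), M >= 1)
  at <- atomTable(chain)
  caRows <- at[at$atomName == "CA", , drop = FALSE]
  ca <- matrix(NA_real_, nResidues(chain), 3)
  ca[caRows$residue, ] <- as.matrix(caRows[, c("x", "y", "z")])
  if (is.na(ca[target, 1]))
    stop("target residue has no Calpha; cannot build a spatial window",
         call. = FALSE)
  others <- setdiff(which(!is.na(ca[, 1])), target)
  d <- sqrt((ca[others, 1] - ca[target, 1])^2 +
            (ca[others, 2] - ca[target, 2])^2 +
            (ca[others, 3] - ca[target, 3])^2)
  nb <- others[order(d, others)]
  c(target, head(nb, M - 1L))
}

.checkMask <- function(mask) {
  stopifnot(is.character(mask), length(mask) >= 1,
            all(mask %in% FEATURE_NAMES), !anyDuplicated(mask))
  FEATURE_NAMES[FEATURE_NAMES %in% mask]  # canonical order
}

#' Length of a structure feature vector
#' @param M spatial window size.
#' @param mask feature subset (any of `"pssm"`, `"rasa"`, `"dpx"`, `"cx"`).
#' @return integer vector length.
#' @export
structureVectorLength <- function(M, mask = FEATURE_NAMES) {
  M * sum(.FEATURE_WIDTH[.checkMask(mask)])
}

#' Structure-path feature vector of one residue
#'
#' @param window residue indices from [spatialWindow()].
#' @param profile scaled profile matrix ([scalePssm()]), rows aligned with
#'   residues; required iff `"pssm"` is in the mask.
#' @param geometry result of [geometryFeatures()], rows aligned with
#'   residues; required iff any of `"rasa"`, `"dpx"`, `"cx"` is in the mask.
#' @param M nominal window size; windows shorter than `M` are zero-padded
#'   at the tail.
#' @param mask feature subset; default all four blocks.
#' @return numeric vector of length `structureVectorLength(M, mask)`,
#'   values in `[0, 1]`.
#' @export
encodeStructure <- function(window, profile = NULL, geometry = NULL,
                            M = 15L, mask = FEATURE_NAMES) {
  mask <- .checkMask(mask)
  stopifnot(length(window) <= M)
  width <- sum(.FEATURE_WIDTH[mask])
  out <- matrix(0, nrow = M, ncol = width)
  needGeom <- any(c("rasa", "dpx", "cx") %in% mask)
  if ("pssm" %in% mask && (is.null(profile) || max(window) > nrow(profile)))
    stop("scaled profile missing for a window member", call. = FALSE)
  if (needGeom && (is.null(geometry) || max(window) > nrow(geometry) ||
                   anyNA(geometry[window, ])))
    stop("geometry features missing for a window member", call. = FALSE)
  for (j in seq_along(window)) {
    block <- numeric(0)
    for (f in mask) {
      block <- c(block, switch(f,
        pssm = as.numeric(profile[window[j], ]),
        rasa = geometry$rasa[window[j]],
        dpx = as.numeric(geometry[window[j], paste0("dpx", 1:6)]),
        cx = as.numeric(geometry[window[j], paste0("cx", 1:6)])))
    }
    out[j, ] <- block
  }
  as.vector(t(out))
}

#' Sequence-path PSSM feature vector of one residue
#'
#' Concatenates the scaled profile rows of the `N` positions centred on
#' the target; positions beyond either terminus contribute 20 zeros.
#'
#' @param profile scaled profile matrix ([scalePssm()]).
#' @param target 1-based position.
#' @param N odd sliding-window size (default 17).
#' @return numeric vector of length `20 * N`.
#' @export
encodeSequencePssm <- function(profile, target, N = 17L) {
  if (N %% 2L == 0L) stop("sliding window size N must be odd", call. = FALSE)
  stopifnot(target >= 1, target <= nrow(profile))
  half <- (N - 1L) / 2L
  pos <- (target - half):(target + half)
  out <- matrix(0, N, 20L)
  ok <- pos >= 1L & pos <= nrow(profile)
  out[ok, ] <- profile[pos[ok], , drop = FALSE]
  as.vector(t(out))
}

#' Sequence-path binary (one-hot) feature vector of one residue
#'
#' Each of the `N` window positions contributes a 21-bit pattern: one bit
#' per standard amino-acid type plus one terminus/unknown bit.
#'
#' @param sequence one-letter amino-acid string.
#' @param target 1-based position.
#' @param N odd sliding-window size.
#' @return numeric 0/1 vector of length `21 * N` with exactly `N` set bits.
#' @export
encodeSequenceBinary <- function(sequence, target, N = 17L) {
  if (N %% 2L == 0L) stop("sliding window size N must be odd", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  stopifnot(target >= 1, target <= length(chars))
  half <- (N - 1L) / 2L
  pos <- (target - half):(target + half)
  out <- matrix(0, N, 21L)
  for (j in seq_len(N)) {
    if (pos[j] < 1L || pos[j] > length(chars)) { out[j, 21L] <- 1; next }
    col <- match(chars[pos[j]], PSSM_ALPHABET)
    out[j, if (is.na(col)) 21L else col] <- 1
  }
  as.vector(t(out))
}

#' Encode every residue of a chain for one classifier path
#'
#' @param chain a [ChainModel-class].
#' @param profile scaled profile matrix (may be `NULL` for layouts that do
#'   not use it).
#' @param geometry result of [geometryFeatures()] (structure layout only).
#' @param layout `"structure"`, `"seqPssm"` or `"seqBinary"`.
#' @param M,N window sizes.
#' @param mask structure-layout feature subset.
#' @return numeric matrix with one row per residue (rows of residues that
#'   cannot be encoded - no Calpha, unknown type - are `NA` and carry
#'   `FALSE` in the `"scored"` attribute).
#' @export
encodeChain <- function(chain, profile = NULL, geometry = NULL,
                        layout = c("structure", "seqPssm", "seqBinary"),
                        M = 15L, N = 17L, mask = FEATURE_NAMES) {
  layout <- match.arg(layout)
  n <- nResidues(chain)
  res <- residueTable(chain)
  eligible <- res$aa %in% PSSM_ALPHABET
  if (layout == "structure") eligible <- eligible & res$hasCa
  len <- switch(layout,
                structure = structureVectorLength(M, mask),
                seqPssm = 20L * N,
                seqBinary = 21L * N)
  X <- matrix(NA_real_, n, len)
  seqStr <- chainSequence(chain)
  for (i in which(eligible)) {
    X[i, ] <- switch(layout,
      structure = encodeStructure(spatialWindow(chain, i, M), profile,
                                  geometry, M, mask),
      seqPssm = encodeSequencePssm(profile, i, N),
      seqBinary = encodeSequenceBinary(seqStr, i, N))
  }
  attr(X, "scored") <- eligible
  attr(X, "layout") <- sprintf("%s-M%d-N%d-%s", layout, M, N,
                               paste(.checkMask(mask), collapse = "+"))
  X
}

#' Write an encoded dataset in LIBSVM sparse text format
#'
#' @param X feature matrix (rows = residues).
#' @param y 0/1 labels.
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeLibsvm <- function(X, y, file) {
  stopifnot(nrow(X) == length(y))
  lines <- vapply(seq_len(nrow(X)), function(i) {
    nz <- which(X[i, ] != 0)
    paste(c(y[i], sprintf("%d:%.6g", nz, X[i, nz])), collapse = " ")
  }, "")
  writeLines(lines, file)
  invisible(file)
}
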