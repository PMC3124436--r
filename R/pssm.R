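## PSI-BLAST ASCII PSSM ingestion and the conservation features derived
## from it.  Only the 20-column integer substitution-score block is used;
## scores are logistic-scaled into (0,1) before entering feature vectors,
## and the diagonal (own-residue) raw score measures conservation.

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the dialect produced by `psiblast -out_ascii_pssm`: a header line
#' carrying the amino-acid column letters followed by one row per query
#' position (`index  residue  20 integer scores ...`).  Only the first 20
#' numeric columns (the substitution scores) are retained, reordered to
#' the file's own header so any column permutation is handled.
#'
#' @param file path to the PSSM file.
#' @return a [PssmMatrix-class].
#' @export
readPssm <- function(file) {
  parsePssm(readLines(file))
}

#' @rdname readPssm
#' @param lines character vector of PSSM lines (alternative to `file`).
#' @export
parsePssm <- function(lines) {
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  ## header: the first line whose tokens start with >= 20 single letters
  isHeader <- vapply(toks, function(tk)
    length(tk) >= 20 && all(nchar(tk[1:20]) == 1) &&
      all(tk[1:20] %in% PSSM_ALPHABET), logical(1))
  if (!any(isHeader))
    stop("not a PSI-BLAST ASCII PSSM: no amino-acid header line", call. = FALSE)
  h <- which(isHeader)[1]
  header <- toks[[h]][1:20]
  rows <- list(); seqChars <- character()
  for (k in seq(h + 1, length(toks))) {
    tk <- toks[[k]]
    if (length(tk) == 0L) break          # blank line ends the block
    if (is.na(suppressWarnings(as.integer(tk[1])))) break  # footer
    if (length(tk) < 22)
      stop("truncated PSSM row at line ", k, ": expected >= 20 score columns",
           call. = FALSE)
    sc <- suppressWarnings(as.integer(tk[3:22]))
    if (anyNA(sc))
      stop("non-integer score in PSSM row at line ", k, call. = FALSE)
    seqChars <- c(seqChars, tk[2])
    rows[[length(rows) + 1L]] <- sc
  }
  if (length(rows) == 0L)
    stop("PSSM contains no score rows", call. = FALSE)
  scores <- do.call(rbind, rows)
  colnames(scores) <- header
  scores <- scores[, PSSM_ALPHABET, drop = FALSE]
  new("PssmMatrix", sequence = paste(seqChars, collapse = ""),
      scores = scores)
}

#' Write a PssmMatrix in PSI-BLAST ASCII dialect
#'
#' Emits a file that [readPssm()] (and PSI-BLAST-aware tools) can read:
#' the two standard comment lines, the 40-letter header, one row per
#' position with the 20 integer scores followed by a zeroed
#' percentage block and the two trailing information columns.
#'
#' @param pssm a [PssmMatrix-class].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writePssm <- function(pssm, file) {
  stopifnot(is(pssm, "PssmMatrix"))
  sc <- pssmScores(pssm)
  seqc <- strsplit(pssmSequence(pssm), "")[[1]]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ",
                      paste(sprintf("%3s", PSSM_ALPHABET), collapse = ""),
                      paste(sprintf("%4s", PSSM_ALPHABET), collapse = ""))),
             con)
  for (i in seq_len(nrow(sc))) {
    writeLines(sprintf("%5d %s  %s %s  %5.2f %9.2f", i, seqc[i],
                       paste(sprintf("%3d", sc[i, ]), collapse = ""),
                       paste(sprintf("%4d", rep(0L, 20)), collapse = ""),
                       0, 0), con)
  }
  writeLines("", con)
  invisible(file)
}

#' Logistic-scaled sequence profile
#'
#' Elementwise `1 / (1 + exp(-x))` applied to the raw integer scores,
#' mapping them into (0, 1).
#'
#' @param pssm a [PssmMatrix-class].
#' @return numeric matrix, positions x 20, strictly inside (0, 1), columns
#'   in PSI-BLAST order.
#' @export
scalePssm <- function(pssm) {
  stopifnot(is(pssm, "PssmMatrix"))
  logisticScale(pssmScores(pssm))
}

#' Conservation score of a position
#'
#' The diagonal element of the PSSM: the substitution score of the query
#' residue's own type at that position.  High values mark evolutionarily
#' conserved positions.
#'
#' @param pssm a [PssmMatrix-class].
#' @param position 1-based position index (vectorised).
#' @return integer score(s).
#' @export
conservationScore <- function(pssm, position = seq_len(nchar(pssmSequence(pssm)))) {
  stopifnot(is(pssm, "PssmMatrix"),
            all(position >= 1), all(position <= nchar(pssmSequence(pssm))))
  aa <- strsplit(pssmSequence(pssm), "")[[1]][position]
  col <- match(aa, PSSM_ALPHABET)
  if (anyNA(col))
    stop("conservation score undefined for non-standard residue at position ",
         paste(position[is.na(col)], collapse = ", "), call. = FALSE)
  pssmScores(pssm)[cbind(position, col)]
}
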