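## Central S4 containers.  Atom coordinates live in per-chain data.frames
## (one row per heavy atom) rather than per-atom objects: every geometric
## descriptor is a vectorised operation over those tables.

#' ChainModel: one polymer chain of a protein structure
#'
#' Holds the heavy atoms of a single chain, grouped into residues in file
#' order.  Hydrogens, waters and HET groups never enter a `ChainModel`.
#'
#' @slot chainId single-letter chain identifier.
#' @slot atoms `data.frame` with one row per heavy atom: `residue`
#'   (1-based residue index), `resKey` (author residue number plus
#'   insertion code), `resName` (PDB three-letter name), `aa` (one-letter
#'   code, `"X"` for unknown types), `atomName`, `element`, `x`, `y`, `z`
#'   (Angstrom), `isSidechain`.
#' @slot residues `data.frame` with one row per residue: `resKey`,
#'   `resName`, `aa`, `hasCa`.
#'
#' @seealso [parseStructure()], [chainSequence()]
#' @export
setClass("ChainModel",
  representation(chainId = "character",
                 atoms = "data.frame",
                 residues = "data.frame"))

setValidity("ChainModel", function(object) {
  msg <- character()
  if (length(object@chainId) != 1L)
    msg <- c(msg, "chainId must be a single string")
  need <- c("residue", "resKey", "resName", "aa", "atomName", "element",
            "x", "y", "z", "isSidechain")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@residues) < 1L)
      msg <- c(msg, "a chain must contain at least one residue")
    if (nrow(object@atoms) < 1L)
      msg <- c(msg, "a chain must contain at least one atom")
    if (nrow(object@atoms) && !all(is.finite(as.matrix(object@atoms[, c("x", "y", "z")]))))
      msg <- c(msg, "atom coordinates must be finite")
    if (nrow(object@atoms) &&
        (min(object@atoms$residue) < 1L ||
         max(object@atoms$residue) > nrow(object@residues)))
      msg <- c(msg, "atom residue indices out of range")
    if (!all(tabulate(object@atoms$residue, nbins = nrow(object@residues)) >= 1L))
      msg <- c(msg, "every residue needs at least one atom")
    if (any(object@atoms$element == ""))
      msg <- c(msg, "atom elements must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' HemeGroup: the heavy atoms of one heme ligand
#'
#' @slot hetCode HET group code (normally `"HEM"`).
#' @slot atoms `data.frame` with columns `atomName`, `element`, `x`, `y`,
#'   `z` (Angstrom), one row per heavy atom.
#' @slot structureId identifier of the parent structure (may be `""`).
#' @export
setClass("HemeGroup",
  representation(hetCode = "character",
                 atoms = "data.frame",
                 structureId = "character"))

setValidity("HemeGroup", function(object) {
  msg <- character()
  if (nrow(object@atoms) < 1L)
    msg <- c(msg, "a heme group must contain at least one atom")
  if (!all(c("atomName", "element", "x", "y", "z") %in% names(object@atoms)))
    msg <- c(msg, "atoms must have columns atomName, element, x, y, z")
  if (length(msg)) msg else TRUE
})

#' PssmMatrix: a PSI-BLAST position-specific scoring matrix
#'
#' Raw integer substitution scores, one row per query residue, twenty
#' columns in PSI-BLAST order (`A R N D C Q E G H I L K M F P S T V W Y`).
#'
#' @slot sequence the query sequence (one-letter codes).
#' @slot scores integer matrix, `nchar(sequence)` x 20.
#' @seealso [parsePssm()], [scalePssm()], [conservationScore()]
#' @export
setClass("PssmMatrix",
  representation(sequence = "character",
                 scores = "matrix"))

setValidity("PssmMatrix", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L)
    msg <- c(msg, "sequence must be a single string")
  else {
    if (ncol(object@scores) != 20L)
      msg <- c(msg, "scores must have exactly 20 columns")
    if (nrow(object@scores) != nchar(object@sequence))
      msg <- c(msg, "row count must equal sequence length")
    if (!identical(colnames(object@scores), PSSM_ALPHABET))
      msg <- c(msg, "score columns must be named in PSI-BLAST order")
  }
  if (length(msg)) msg else TRUE
})

#' LabeledChain: a chain with per-residue binding labels
#'
#' @slot chain a [ChainModel-class].
#' @slot labels integer vector, one entry per residue; 1 = heme-binding,
#'   0 = non-binding.
#' @export
setClass("LabeledChain",
  representation(chain = "ChainModel",
                 labels = "integer"))

setValidity("LabeledChain", function(object) {
  msg <- character()
  if (length(object@labels) != nResidues(object@chain))
    msg <- c(msg, "one label per residue required")
  if (!all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChainModel", function(object) {
  cat(sprintf("ChainModel '%s': %d residues, %d heavy atoms\n",
              object@chainId, nrow(object@residues), nrow(object@atoms)))
  s <- chainSequence(object)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" sequence:", s, "\n")
})

setMethod("show", "HemeGroup", function(object) {
  cat(sprintf("HemeGroup '%s': %d heavy atoms\n",
              object@hetCode, nrow(object@atoms)))
})

setMethod("show", "PssmMatrix", function(object) {
  cat(sprintf("PssmMatrix: %d positions x 20 scores, range [%d, %d]\n",
              nrow(object@scores), min(object@scores), max(object@scores)))
})

setMethod("show", "LabeledChain", function(object) {
  cat(sprintf("LabeledChain '%s': %d residues (%d binding, %d non-binding)\n",
              chainId(object@chain), length(object@labels),
              sum(object@labels == 1L), sum(object@labels == 0L)))
})
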