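## Shared constant tables: amino-acid alphabets, maximum accessible surface
## areas, van der Waals radii.  Column order of all PSSM-derived matrices
## follows the PSI-BLAST convention.

#' @importFrom methods new validObject is slot
#' @importFrom stats sd ks.test predict runif rnorm
#' @importFrom utils head write.table read.table
NULL

## PSI-BLAST column order (one-letter codes)
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

## three-letter -> one-letter for the 20 standard types
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

## common non-standard residues with an accepted standard parent;
## anything absent from both tables becomes UNK ("X") and is excluded
## from training/prediction sets.
AA_NONSTANDARD_MAP <- c(
  MSE = "M",  # selenomethionine
  SEC = "C",  # selenocysteine (nearest standard: Cys)
  PYL = "K",  # pyrrolysine
  HYP = "P",  # hydroxyproline
  SEP = "S", TPO = "T", PTR = "Y",  # phosphorylated
  CSO = "C", CME = "C", CSD = "C",  # modified cysteines
  MLY = "K", M3L = "K", KCX = "K",
  FME = "M")

AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE), names = AA_THREE_TO_ONE)

## Maximum solvent accessible surface area per residue type (Rost & Sander,
## 1994), in squared Angstroms; denominator of the relative accessibility.
MAX_SASA <- c(
  A = 106, R = 248, N = 157, D = 163, C = 135,
  Q = 198, E = 194, G = 84,  H = 184, I = 169,
  L = 164, K = 205, M = 188, F = 197, P = 136,
  S = 130, T = 142, V = 142, W = 227, Y = 222)

## van der Waals radii (Angstrom) for heavy elements; default for anything
## else (metals etc.) is the carbon radius.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_DEFAULT <- 1.70

## Backbone atom names; everything else counts as side chain.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Standard logistic function
#'
#' Maps any real value to (0, 1) via `1 / (1 + exp(-x))`.  All raw PSSM
#' scores and the six depth/protrusion statistics are passed through this
#' scaling before entering a feature vector.
#'
#' @param x numeric vector or matrix.
#' @return object of the same shape with values in (0, 1).
#' @examples
#' logisticScale(c(-3, 0, 1))
#' @export
logisticScale <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  1 / (1 + exp(-x))
}
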