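## Structure-derived per-residue descriptors, computed on the unbound
## chain (heme atoms never participate):
##   SASA  - Shrake-Rupley numerical accessible surface, per heavy atom;
##   RASA  - residue SASA / maximum SASA of its type (Rost & Sander);
##   DPX   - atom depth: distance to the nearest solvent-accessible atom;
##   CX    - atom protrusion: empty/occupied volume ratio in a 10 A sphere.
## DPX and CX are summarised per residue by six statistics (mean and sd
## over all atoms, mean and sd over side-chain atoms, min, max) and passed
## through the logistic function before entering feature vectors.

## Deterministic quasi-uniform unit sphere points (golden-spiral lattice).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atomRadii <- function(elements) {
  r <- VDW_RADII[elements]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

## numerical threshold below which a quadrature SASA counts as "buried"
SASA_EPS <- 1e-6

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Places a quasi-uniform point lattice on each atom's solvent-expanded
#' sphere (van der Waals radius + probe radius) and counts the points not
#' occluded by any other expanded sphere.  Per-residue SASA is the sum
#' over the residue's atoms.
#'
#' @param chain a [ChainModel-class].
#' @param probeRadius solvent probe radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param nPoints lattice points per atom (default 960).
#' @return list with `perAtom` (numeric, one value per atom row, A^2) and
#'   `perResidue` (numeric, one value per residue, A^2).
#' @export
computeSasa <- function(chain, probeRadius = 1.4, nPoints = 960L) {
  stopifnot(is(chain, "ChainModel"), probeRadius > 0, nPoints >= 12)
  at <- atomTable(chain)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- .atomRadii(at$element) + probeRadius
  n <- nrow(xyz)
  pts <- .spherePoints(nPoints)
  perAtom <- numeric(n)
  ## neighbour prefilter: spheres can only intersect within r_i + max(r_j)
  maxR <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + maxR)^2 & d2 > 0)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    if (length(nb) == 0L) {
      perAtom[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & (dj2 > r[j]^2)
    }
    perAtom[i] <- 4 * pi * r[i]^2 * sum(free) / nPoints
  }
  perResidue <- as.vector(tapply(perAtom, factor(at$residue,
                                                 levels = seq_len(nResidues(chain))),
                                 sum))
  perResidue[is.na(perResidue)] <- 0
  list(perAtom = perAtom, perResidue = perResidue)
}

#' Relative solvent accessibility per residue
#'
#' Residue SASA divided by the maximum SASA of its amino-acid type
#' (Rost & Sander 1994 constants), clamped to `[0, 1]` (numerical SASA of
#' terminal residues can exceed the tabulated maximum).
#'
#' @param chain a [ChainModel-class].
#' @param sasa result of [computeSasa()] for the same chain.
#' @return numeric vector, one value in `[0, 1]` per residue; `NA` (with a
#'   warning) for residues of unknown type, which have no maximum constant.
#' @export
computeRasa <- function(chain, sasa) {
  stopifnot(is(chain, "ChainModel"))
  aa <- residueTable(chain)$aa
  mx <- MAX_SASA[aa]
  if (anyNA(mx))
    warning("no max-SASA constant for residue type X; RASA set to NA")
  pmin(pmax(sasa$perResidue / unname(mx), 0), 1)
}

.sixStats <- function(values, sidechain) {
  ## side-chain statistics fall back to all-atom statistics when the
  ## residue has no side-chain atoms (glycine)
  sdv <- function(v) if (length(v) > 1L) sd(v) else 0
  sc <- values[sidechain]
  if (length(sc) == 0L) sc <- values
  c(meanAll = mean(values), sdAll = sdv(values),
    meanSide = mean(sc), sdSide = sdv(sc),
    min = min(values), max = max(values))
}

#' Residue depth index statistics
#'
#' Atom depth (DPX) is 0 for solvent-accessible atoms (SASA > 0) and the
#' Euclidean distance to the closest accessible atom otherwise.  Per
#' residue the six statistics (mean/sd over all atoms, mean/sd over
#' side-chain atoms, min, max) are returned unscaled (Angstrom).
#'
#' @param chain a [ChainModel-class].
#' @param sasa result of [computeSasa()] for the same chain.
#' @return numeric matrix, residues x 6
#'   (`meanAll, sdAll, meanSide, sdSide, min, max`).
#' @export
computeDpx <- function(chain, sasa) {
  stopifnot(is(chain, "ChainModel"))
  at <- atomTable(chain)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  acc <- sasa$perAtom > SASA_EPS
  if (!any(acc))
    stop("degenerate chain: no solvent-accessible atoms", call. = FALSE)
  depth <- numeric(nrow(xyz))
  buried <- which(!acc)
  if (length(buried)) {
    axyz <- xyz[acc, , drop = FALSE]
    for (i in buried) {
      d2 <- (axyz[, 1] - xyz[i, 1])^2 + (axyz[, 2] - xyz[i, 2])^2 +
        (axyz[, 3] - xyz[i, 3])^2
      depth[i] <- sqrt(min(d2))
    }
  }
  t(vapply(seq_len(nResidues(chain)), function(ri) {
    sel <- at$residue == ri
    .sixStats(depth[sel], at$isSidechain[sel])
  }, numeric(6)))
}

#' Residue protrusion index statistics
#'
#' For each atom, the occupied volume inside a sphere of radius
#' `sphereRadius` is estimated as (number of heavy atoms within the
#' sphere, including the atom itself) x `meanAtomVolume`; CX is the ratio
#' of the remaining (external) volume to the occupied volume, floored at 0.
#' High CX marks protruding atoms, low CX concavities and the interior.
#'
#' @param chain a [ChainModel-class].
#' @param sphereRadius sphere radius in Angstrom (default 10).
#' @param meanAtomVolume mean heavy-atom volume in cubic Angstrom
#'   (default 20.1).
#' @return numeric matrix, residues x 6, unscaled, same column layout as
#'   [computeDpx()].
#' @export
computeCx <- function(chain, sphereRadius = 10, meanAtomVolume = 20.1) {
  stopifnot(is(chain, "ChainModel"), sphereRadius > 0, meanAtomVolume > 0)
  at <- atomTable(chain)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  vSphere <- 4 / 3 * pi * sphereRadius^3
  r2 <- sphereRadius^2
  cx <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    vInt <- sum(d2 <= r2) * meanAtomVolume  # includes the atom itself
    cx[i] <- max(vSphere - vInt, 0) / vInt
  }
  t(vapply(seq_len(nResidues(chain)), function(ri) {
    sel <- at$residue == ri
    .sixStats(cx[sel], at$isSidechain[sel])
  }, numeric(6)))
}

#' Per-residue geometry feature block
#'
#' Assembles RASA plus the logistic-scaled six-statistic DPX and CX blocks
#' into the 13-column geometry part of the residue descriptor.
#'
#' @param chain a [ChainModel-class].
#' @param probeRadius,nPoints passed to [computeSasa()].
#' @param sphereRadius,meanAtomVolume passed to [computeCx()].
#' @return `data.frame` with columns `rasa`, `dpx1..dpx6`, `cx1..cx6`,
#'   one row per residue, all values in `[0, 1]`.
#' @export
geometryFeatures <- function(chain, probeRadius = 1.4, nPoints = 960L,
                             sphereRadius = 10, meanAtomVolume = 20.1) {
  sasa <- computeSasa(chain, probeRadius, nPoints)
  rasa <- computeRasa(chain, sasa)
  dpx <- logisticScale(computeDpx(chain, sasa))
  cx <- logisticScale(computeCx(chain, sphereRadius, meanAtomVolume))
  out <- data.frame(rasa = rasa, dpx, cx)
  names(out) <- c("rasa", paste0("dpx", 1:6), paste0("cx", 1:6))
  rownames(out) <- residueTable(chain)$resKey
  out
}

#' Export geometry features as TSV
#'
#' One row per residue: chain, position, amino acid, then the 13 geometry
#' columns of [geometryFeatures()].
#'
#' @param chain a [ChainModel-class].
#' @param features result of [geometryFeatures()].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeGeometryTsv <- function(chain, features, file) {
  res <- residueTable(chain)
  out <- cbind(chain = chainId(chain), position = res$resKey, aa = res$aa,
               features)
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
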