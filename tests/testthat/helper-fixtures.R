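# In-code fixtures shared across test files.

# Minimal ChainModel built straight from coordinates: one pseudo-residue
# per row block. `atoms` is a data.frame with atomName, element, x, y, z
# and a residue index column.
chainFromAtoms <- function(atoms, aa = NULL, chainId = "A") {
  n <- max(atoms$residue)
  if (is.null(aa)) aa <- rep("A", n)
  atoms$resKey <- as.character(atoms$residue)
  atoms$resName <- unname(hemescan:::AA_ONE_TO_THREE[aa])[atoms$residue]
  atoms$aa <- aa[atoms$residue]
  atoms$isSidechain <- !(atoms$atomName %in% c("N", "CA", "C", "O", "OXT"))
  residues <- data.frame(resKey = as.character(seq_len(n)),
                         resName = unname(hemescan:::AA_ONE_TO_THREE[aa]),
                         aa = aa,
                         hasCa = vapply(seq_len(n), function(i)
                           any(atoms$atomName[atoms$residue == i] == "CA"),
                           logical(1)),
                         stringsAsFactors = FALSE)
  methods::new("ChainModel", chainId = chainId, atoms = atoms,
               residues = residues)
}

# single atom per residue, each named CA so spatial windows work
caOnlyChain <- function(xyz, aa = NULL, chainId = "A") {
  chainFromAtoms(data.frame(residue = seq_len(nrow(xyz)), atomName = "CA",
                            element = "C", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE),
                 aa = aa, chainId = chainId)
}

hemeFromXyz <- function(xyz) {
  methods::new("HemeGroup", hetCode = "HEM",
               atoms = data.frame(atomName = sprintf("C%02d", seq_len(nrow(xyz))),
                                  element = "C", x = xyz[, 1], y = xyz[, 2],
                                  z = xyz[, 3], stringsAsFactors = FALSE),
               structureId = "test")
}

# octahedral cage: six atoms at +-d on each axis around a central atom
octahedralCage <- function(d = 2.2) {
  xyz <- rbind(c(0, 0, 0),
               c(d, 0, 0), c(-d, 0, 0),
               c(0, d, 0), c(0, -d, 0),
               c(0, 0, d), c(0, 0, -d))
  chainFromAtoms(data.frame(residue = seq_len(7), atomName = "CA",
                            element = "C", x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3], stringsAsFactors = FALSE))
}

# independent Monte-Carlo SASA oracle (random directions, not the
# package's deterministic spiral lattice)
sasaOracle <- function(chain, probe = 1.4, nPoints = 9600, seed = 42) {
  at <- atomTable(chain)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- hemescan:::.atomRadii(at$element) + probe
  set.seed(seed)
  u <- matrix(rnorm(nPoints * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  vapply(seq_len(nrow(xyz)), function(i) {
    p <- u * r[i]
    p[, 1] <- p[, 1] + xyz[i, 1]; p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, nPoints)
    for (j in seq_len(nrow(xyz))[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & (d2 > r[j]^2)
    }
    4 * pi * r[i]^2 * mean(free)
  }, 0)
}

# brute-force per-atom depth: 0 if accessible, else min distance over an
# explicit double loop to accessible atoms
dpxOracle <- function(chain, sasa) {
  at <- atomTable(chain)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  acc <- which(sasa$perAtom > 1e-6)
  vapply(seq_len(nrow(xyz)), function(i) {
    if (i %in% acc) return(0)
    best <- Inf
    for (j in acc) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < best) best <- d
    }
    best
  }, 0)
}

# brute-force per-atom protrusion via an explicit neighbour count
cxOracle <- function(chain, R = 10, v = 20.1) {
  at <- atomTable(chain)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  vapply(seq_len(n), function(i) {
    cnt <- 0L
    for (j in seq_len(n))
      if (sum((xyz[i, ] - xyz[j, ])^2) <= R^2) cnt <- cnt + 1L
    vi <- cnt * v
    max(4 / 3 * pi * R^3 - vi, 0) / vi
  }, 0)
}

# tiny deterministic PSSM text in the PSI-BLAST ASCII dialect
toyPssmLines <- function(seqStr = "ACDEF", scores = NULL) {
  n <- nchar(seqStr)
  if (is.null(scores)) {
    set.seed(99)
    scores <- matrix(sample(-4:8, n * 20, replace = TRUE), n, 20)
  }
  p <- methods::new("PssmMatrix", sequence = seqStr,
                    scores = structure(scores,
                                       dimnames = list(NULL, hemescan:::PSSM_ALPHABET)))
  f <- tempfile()
  writePssm(p, f)
  readLines(f)
}
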