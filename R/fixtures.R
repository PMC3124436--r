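## Self-contained synthetic heme-protein complexes.
##
## Chains are ideal helices (3.8 A Calpha spacing, 1.5 A rise, 100 deg
## twist) either straight or packed as a three-helix bundle; each residue
## carries four backbone atoms plus one pseudo side-chain atom 2.4 A from
## the Calpha along the outward normal.  A planar porphyrin-like heavy-atom
## grid stands in for the heme: it is pushed into an exterior groove of
## the scaffold until every scaffold atom keeps a clearance margin, then
## the side chains of the `patchSize` nearest residues are re-oriented to
## reach within the contact cutoff.  That construction guarantees closure:
## distance labelling of the emitted structure reproduces the planted
## truth exactly, which is verified before the fixture is returned.
##
## Profiles mimic the conservation signal of real binding sites:
## predominantly negative discretised Gaussian background scores in
## [-4, 4], with the diagonal (own-residue) score raised by
## `conservationBoost` (capped at 12) at planted positions.  Patch
## residues are preferentially Cys/His/Met/Phe, the types
## over-represented in real heme interfaces.

HEME_CLEARANCE <- 5.0   # min heme-to-scaffold atom distance before reach (A)
HEME_REACH <- 4.0       # adjusted side-chain to nearest heme atom distance (A)

#' Fixture specification
#'
#' @param nChains chains in a benchmark (1 for a single toy complex).
#' @param residuesPerChain residues per chain (default 60).
#' @param patchSize planted binding residues per heme (default 8).
#' @param hemesPerChain hemes per chain (default 1).
#' @param conservationBoost added mean diagonal PSSM score at planted
#'   positions (default 8).
#' @param geometryStyle `"helix-bundle"` (three packed helices, gives the
#'   scaffold a core and exterior grooves) or `"helix"` (one straight
#'   helix).
#' @param cutoff contact cutoff the planted patch is built against
#'   (default 4.5 A).
#' @param decoyRate fraction of non-binding residues that are conserved
#'   decoys (default 0.15): they share the interface residue-type bias
#'   and receive the same profile conservation boost, but lie scattered
#'   over the scaffold.  Real chains always contain conserved
#'   non-interface residues (structural cores, disulfides, other sites);
#'   they are what windowed context and spatial filtering must overcome.
#' @param seed integer seed; every random choice derives from it.
#' @return a `fixtureSpec` list.
#' @export
fixtureSpec <- function(nChains = 1L, residuesPerChain = 60L, patchSize = 8L,
                        hemesPerChain = 1L, conservationBoost = 8,
                        geometryStyle = c("helix-bundle", "helix"),
                        cutoff = 4.5, decoyRate = 0.15, seed = 1L) {
  geometryStyle <- match.arg(geometryStyle)
  stopifnot(patchSize >= 1, patchSize * hemesPerChain < residuesPerChain,
            conservationBoost >= 0, nChains >= 1, hemesPerChain >= 1,
            decoyRate >= 0, decoyRate < 1)
  structure(list(nChains = as.integer(nChains),
                 residuesPerChain = as.integer(residuesPerChain),
                 patchSize = as.integer(patchSize),
                 hemesPerChain = as.integer(hemesPerChain),
                 conservationBoost = conservationBoost,
                 geometryStyle = geometryStyle,
                 cutoff = cutoff, decoyRate = decoyRate,
                 seed = as.integer(seed)),
            class = "fixtureSpec")
}

## ideal-helix scaffold; returns per-residue atom rows and helix metadata
.buildScaffold <- function(n, style) {
  if (style == "helix") {
    centers <- matrix(c(0, 0), 1)
    seg <- rep(1L, n)
  } else {
    centers <- rbind(c(0, 0), c(8.6, 0), c(4.3, 7.45))
    per <- ceiling(n / 3)
    seg <- rep(1:3, each = per)[seq_len(n)]
  }
  within <- unlist(lapply(split(seq_len(n), seg), seq_along), use.names = FALSE)
  segLen <- as.vector(table(seg))[seg]
  dirUp <- seg %% 2L == 1L  # antiparallel packing, aligned z ranges
  t <- within * (100 * pi / 180)
  z <- ifelse(dirUp, within, segLen + 1L - within) * 1.5
  cx <- centers[seg, 1]; cy <- centers[seg, 2]
  helix <- function(radius, phase, dz)
    cbind(cx + radius * cos(t + phase), cy + radius * sin(t + phase), z + dz)
  ca <- helix(2.3, 0, 0)
  atoms <- list(N = helix(1.9, -0.53, -0.9), CA = ca,
                C = helix(2.0, 0.45, 0.6), O = helix(2.0, 0.47, 1.8))
  outward <- cbind(ca[, 1] - cx, ca[, 2] - cy, 0)
  outward <- outward / sqrt(rowSums(outward^2))
  ## pseudo side-chain lengths vary as real residue sizes do
  cbLen <- runif(n, 1.5, 4.0)
  atoms$CB <- ca + cbLen * outward
  list(atoms = atoms, seg = seg, centers = centers, ca = ca)
}

## planar porphyrin-like grid of 43 heavy atoms spanned by unit vectors
## e1, e2 around `center`
.hemeAtoms <- function(center, e1, e2) {
  g <- expand.grid(i = -3:3, j = -3:3)
  g <- g[order(g$i^2 + g$j^2, g$i, g$j), ][1:43, ]
  xyz <- center[rep(1, 43), , drop = FALSE] +
    1.4 * (g$i %o% e1) + 1.4 * (g$j %o% e2)
  elem <- c("FE", rep("N", 4), rep("C", 38))
  data.frame(atomName = c("FE", paste0("N", 1:4), sprintf("C%02d", 1:38)),
             element = elem, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

.asChainModel <- function(atoms, aa, chain_id = "A") {
  n <- length(aa)
  names4 <- names(atoms)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(residue = i, resKey = as.character(i),
               resName = AA_ONE_TO_THREE[aa[i]], aa = aa[i],
               atomName = names4,
               element = c("N", "C", "C", "O", "C"),
               x = vapply(atoms, function(m) m[i, 1], 0),
               y = vapply(atoms, function(m) m[i, 2], 0),
               z = vapply(atoms, function(m) m[i, 3], 0),
               isSidechain = names4 == "CB",
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(rows) <- NULL
  residues <- data.frame(resKey = as.character(seq_len(n)),
                         resName = unname(AA_ONE_TO_THREE[aa]), aa = aa,
                         hasCa = TRUE, stringsAsFactors = FALSE)
  new("ChainModel", chainId = chain_id, atoms = rows, residues = residues)
}

#' Generate one synthetic heme-protein complex
#'
#' @param spec a [fixtureSpec()].
#' @param chainId chain identifier for the emitted chain.
#' @return list with `chain` (a [ChainModel-class]), `hemes` (list of
#'   [HemeGroup-class]) and `truth` (0/1 integer labels).  The closure
#'   guarantee - [labelBindingResidues()] on the emitted structure equals
#'   `truth` - is verified internally; an infeasible specification stops
#'   with a generation error.
#' @examples
#' fx <- makeToyComplex(fixtureSpec(residuesPerChain = 60, patchSize = 8,
#'                                  seed = 7))
#' sum(fx$truth)
#' @export
makeToyComplex <- function(spec, chainId = "A") {
  stopifnot(inherits(spec, "fixtureSpec"))
  set.seed(spec$seed)
  n <- spec$residuesPerChain
  sc <- .buildScaffold(n, spec$geometryStyle)

  ## amino-acid identities: interface types enriched inside the patch
  ## (assigned after patches are known); start with a uniform background
  aa <- sample(PSSM_ALPHABET, n, replace = TRUE)

  atoms <- sc$atoms
  truth <- rep(0L, n)
  hemes <- list()
  centroid <- colMeans(sc$ca)

  ## candidate outward ray directions: for a bundle, bisectors of the
  ## exterior grooves between helix pairs (heme pockets are clefts);
  ## for a single helix, radial directions
  grooves <- if (spec$geometryStyle == "helix-bundle")
    list(c(1, 2), c(1, 3), c(2, 3)) else list(1L)

  allAtomXyz <- function() do.call(rbind, lapply(atoms, function(m) m))

  for (k in seq_len(spec$hemesPerChain)) {
    placed <- FALSE
    for (try in 1:25) {
      if (spec$geometryStyle == "helix-bundle") {
        gp <- grooves[[sample.int(length(grooves), 1)]]
        mid <- colMeans(sc$centers[gp, , drop = FALSE])
        u <- c(mid - centroid[1:2], 0)
      } else {
        ang <- runif(1, 0, 2 * pi)
        u <- c(cos(ang), sin(ang), 0)
      }
      u <- u / sqrt(sum(u^2))
      zAnchor <- runif(1, min(sc$ca[, 3]) + 8, max(sc$ca[, 3]) - 8)
      origin <- c(centroid[1], centroid[2], zAnchor)
      e1 <- c(0, 0, 1)                        # heme plane: vertical sheet
      e2 <- c(u[2], -u[1], 0)                 # facing the scaffold
      ## slide the heme out along the groove ray to the first depth where
      ## the patch separates: the patchSize nearest (unclaimed) residues
      ## may sit at contact range, every other residue keeps a clearance
      ## margin beyond the cutoff, and nothing clashes sterically
      hd <- NULL
      free <- which(truth == 0L)
      for (D in seq(4, 26, by = 0.25)) {
        cand <- .hemeAtoms(matrix(origin + D * u, 1), e1, e2)
        hxyz <- as.matrix(cand[, c("x", "y", "z")])
        resMin <- vapply(seq_len(n), function(i) {
          axyz <- rbind(atoms$N[i, ], atoms$CA[i, ], atoms$C[i, ],
                        atoms$O[i, ], atoms$CB[i, ])
          min(.pairwiseMinDist(axyz, hxyz))
        }, 0)
        sel <- free[order(resMin[free])][seq_len(spec$patchSize)]
        if (min(resMin) >= 3.2 &&
            min(resMin[-sel]) >= HEME_CLEARANCE &&
            max(resMin[sel]) <= 12) {
          hd <- cand; patch <- sel; patchDist <- resMin
          break
        }
      }
      if (is.null(hd)) next
      hxyz <- as.matrix(hd[, c("x", "y", "z")])
      ## re-orient the side chains of patch residues still out of contact
      ## range so they reach the heme
      newCB <- atoms$CB
      ok <- TRUE
      for (i in patch) {
        if (patchDist[i] <= spec$cutoff - 0.3) next
        dh <- sqrt(colSums((t(hxyz) - sc$ca[i, ])^2))
        j <- which.min(dh)
        dir <- (hxyz[j, ] - sc$ca[i, ]) / dh[j]
        ext <- max(dh[j] - HEME_REACH, 1.2)
        newCB[i, ] <- sc$ca[i, ] + ext * dir
        if (sqrt(sum((newCB[i, ] - hxyz[j, ])^2)) > spec$cutoff - 0.3) {
          ok <- FALSE; break  # Calpha itself too far off this groove
        }
        ## the reach must land inside the cutoff of this heme only
        if (length(hemes)) {
          dOther <- min(vapply(hemes, function(h)
            min(.pairwiseMinDist(newCB[i, , drop = FALSE],
                                 as.matrix(atomTable(h)[, c("x", "y", "z")]))), 0))
          if (dOther <= spec$cutoff + 0.3) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      atoms$CB <- newCB
      truth[patch] <- 1L
      hemes[[length(hemes) + 1L]] <- new("HemeGroup", hetCode = "HEM",
                                         atoms = hd, structureId = "synthetic")
      placed <- TRUE
      break
    }
    if (!placed)
      stop("patch placement infeasible for this fixture specification",
           call. = FALSE)
  }

  ## conserved decoys: small spatial clusters of non-binding residues
  ## that share the interface residue-type bias and (in synthPssm) its
  ## conservation - other functional sites, smaller than a heme pocket
  bg <- which(truth == 0L)
  nDecoy <- round(spec$decoyRate * length(bg))
  decoys <- integer(0)
  while (length(decoys) < nDecoy) {
    free <- setdiff(bg, decoys)
    anchor <- free[sample.int(length(free), 1)]
    d <- sqrt(colSums((t(sc$ca[free, , drop = FALSE]) - sc$ca[anchor, ])^2))
    cluster <- free[order(d)][seq_len(min(3L, length(free)))]
    decoys <- c(decoys, head(cluster, nDecoy - length(decoys)))
  }
  decoys <- sort(decoys)

  ## interface-type enrichment at planted and decoy positions
  for (idx in list(which(truth == 1L), decoys)) {
    enrich <- runif(length(idx)) < 0.8
    aa[idx[enrich]] <- sample(c("C", "H", "M", "F"), sum(enrich),
                              replace = TRUE)
  }

  chain <- .asChainModel(atoms, aa, chainId)
  lab <- suppressWarnings(labelBindingResidues(chain, hemes, spec$cutoff))
  if (!identical(bindingLabels(lab), truth))
    stop("fixture closure violated: distance labelling does not reproduce ",
         "the planted truth", call. = FALSE)
  list(chain = chain, hemes = hemes, truth = truth, decoys = decoys)
}

## min distance from each row of A to the rows of B (returns per-row min)
.pairwiseMinDist <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    sqrt(min((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
             (B[, 3] - A[i, 3])^2)), 0)
}

#' Synthesize a PSSM with a planted conservation signal
#'
#' Emulates two statistical features of real profiles.  First, binding
#' positions are conserved: their diagonal (own-residue) score is raised
#' by `conservationBoost`.  Second, conservation alone does not identify
#' the interface: a fraction `decoyRate` of non-binding positions are
#' conserved decoys (structural cores, catalytic residues) whose diagonal
#' is raised the same way.  True sites form spatial/sequence clusters
#' while decoys are scattered, which is exactly the structure that
#' windowed context and the spatial false-positive filter exploit.
#'
#' @param sequence one-letter query sequence (standard types only).
#' @param truth 0/1 labels aligned with the sequence.
#' @param conservationBoost added diagonal score at label-1 positions
#'   (and at decoy positions); final diagonal capped at 12.
#' @param seed integer seed.
#' @param decoys indices of conserved non-binding positions (from
#'   [makeToyComplex()]); empty by default.
#' @return a [PssmMatrix-class].  Background scores are discretised
#'   Gaussian noise (mean -2, sd 1.5) truncated to `[-4, 4]`: substitution
#'   scores of unrelated residues are predominantly negative, so strongly
#'   positive background scores are as rare as in real profiles.
#' @export
synthPssm <- function(sequence, truth, conservationBoost = 8, seed = 1L,
                      decoys = integer(0)) {
  stopifnot(conservationBoost >= 0, nchar(sequence) == length(truth),
            all(truth[decoys] == 0L))
  set.seed(seed)
  n <- nchar(sequence)
  scores <- matrix(pmax(-4L, pmin(4L, as.integer(round(rnorm(n * 20L, -2, 1.5))))),
                   n, 20L)
  colnames(scores) <- PSSM_ALPHABET
  chars <- strsplit(sequence, "")[[1]]
  col <- match(chars, PSSM_ALPHABET)
  if (anyNA(col)) stop("sequence contains non-standard residues")
  pos <- c(which(truth == 1L), as.integer(decoys))
  scores[cbind(pos, col[pos])] <-
    pmin(scores[cbind(pos, col[pos])] + round(conservationBoost), 12L)
  new("PssmMatrix", sequence = sequence, scores = scores)
}

#' Generate a benchmark dataset on disk
#'
#' Writes `chainNN.pdb`, `chainNN.pssm` and a pooled `truth.tsv` under
#' `dir`, exactly the layout the pipeline consumes; bit-for-bit
#' reproducible for a given seed.
#'
#' @param spec a [fixtureSpec()] with `nChains >= 1`.
#' @param dir output directory (created if missing).
#' @return invisibly, a list of per-chain sample lists
#'   (`chain`, `hemes`, `truth`, `pssm`, `id`).
#' @export
makeBenchmark <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- vector("list", spec$nChains)
  truthRows <- list()
  for (k in seq_len(spec$nChains)) {
    cs <- spec
    cs$seed <- spec$seed * 1009L + k   # independent per-chain stream
    fx <- makeToyComplex(cs)
    id <- sprintf("chain%02d", k)
    pssm <- synthPssm(chainSequence(fx$chain), fx$truth,
                      spec$conservationBoost, seed = cs$seed + 5000L,
                      decoys = fx$decoys)
    writeComplexPdb(fx$chain, fx$hemes,
                    file.path(dir, paste0(id, ".pdb")))
    writePssm(pssm, file.path(dir, paste0(id, ".pssm")))
    res <- residueTable(fx$chain)
    truthRows[[k]] <- data.frame(id = id, position = res$resKey,
                                 aa = res$aa, label = fx$truth)
    samples[[k]] <- list(chain = fx$chain, hemes = fx$hemes,
                         truth = fx$truth, pssm = pssm, id = id)
  }
  write.table(do.call(rbind, truthRows), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(samples)
}

#' Load a benchmark directory written by [makeBenchmark()]
#'
#' @param dir benchmark directory.
#' @param cutoff contact cutoff used to re-derive labels from the
#'   structures (default 4.5 A).
#' @return list of per-chain sample lists as in [makeBenchmark()].
#' @export
loadBenchmark <- function(dir, cutoff = 4.5) {
  pdbs <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(pdbs) == 0L) stop("no PDB files under ", dir, call. = FALSE)
  lapply(pdbs, function(f) {
    id <- sub("\\.pdb$", "", basename(f))
    st <- readStructure(f)
    chain <- st$chains[[1]]
    pssmFile <- file.path(dir, paste0(id, ".pssm"))
    pssm <- if (file.exists(pssmFile)) readPssm(pssmFile) else NULL
    if (!is.null(pssm) &&
        nchar(pssmSequence(pssm)) != nResidues(chain))
      stop("PSSM/structure length mismatch for ", id, call. = FALSE)
    lab <- suppressWarnings(labelBindingResidues(chain, st$hemes, cutoff))
    list(chain = chain, hemes = st$hemes, truth = bindingLabels(lab),
         pssm = pssm, id = id)
  })
}
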