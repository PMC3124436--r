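## Heme-contact labelling and descriptive interface statistics.  The
## contact criterion is a heavy-atom distance cutoff (default 4.5 A): a
## residue is heme-binding iff any of its heavy atoms lies within the
## cutoff of any heavy atom of any heme in the structure.

.minDistToHemes <- function(chain, hemes) {
  at <- atomTable(chain)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  hxyz <- do.call(rbind, lapply(hemes, function(h)
    as.matrix(atomTable(h)[, c("x", "y", "z")])))
  ## per chain atom, squared distance to the nearest heme atom
  dmin2 <- rep(Inf, nrow(xyz))
  for (k in seq_len(nrow(hxyz))) {
    d2 <- (xyz[, 1] - hxyz[k, 1])^2 + (xyz[, 2] - hxyz[k, 2])^2 +
      (xyz[, 3] - hxyz[k, 3])^2
    dmin2 <- pmin(dmin2, d2)
  }
  sqrt(as.vector(tapply(dmin2, factor(at$residue, levels = seq_len(nResidues(chain))),
                        min)))
}

#' Label heme-binding residues by atomic contact
#'
#' @param chain a [ChainModel-class].
#' @param hemes list of [HemeGroup-class]; with several hemes the label
#'   set is the union over all of them.
#' @param cutoff heavy-atom contact distance in Angstrom (default 4.5).
#' @return a [LabeledChain-class].  An empty heme list yields all-zero
#'   labels with a warning.
#' @export
labelBindingResidues <- function(chain, hemes, cutoff = 4.5) {
  stopifnot(is(chain, "ChainModel"), cutoff > 0)
  if (length(hemes) == 0L) {
    warning("no heme groups supplied; all residues labelled non-binding")
    return(new("LabeledChain", chain = chain,
               labels = rep(0L, nResidues(chain))))
  }
  d <- .minDistToHemes(chain, hemes)
  new("LabeledChain", chain = chain, labels = as.integer(d <= cutoff))
}

#' Interface propensity per amino-acid type
#'
#' Log2 ratio between each type's frequency among binding residues and
#' its frequency among the remaining residues, pooled over a dataset.
#' Heme pockets are typically enriched in Cys, His, Met and Phe.
#'
#' @param dataset list of [LabeledChain-class].
#' @return `data.frame` with one row per amino-acid type: `aa`,
#'   `freqInterface`, `freqRest`, `log2Ratio` (`NA` when either frequency
#'   is zero, flagged in `undefined`).
#' @export
interfacePropensity <- function(dataset) {
  aa <- unlist(lapply(dataset, function(lc) residueTable(lc)$aa))
  lab <- unlist(lapply(dataset, bindingLabels))
  keep <- aa %in% PSSM_ALPHABET
  aa <- aa[keep]; lab <- lab[keep]
  if (!any(lab == 1L) || !any(lab == 0L))
    stop("dataset must contain both binding and non-binding residues",
         call. = FALSE)
  fi <- table(factor(aa[lab == 1L], levels = PSSM_ALPHABET))
  fr <- table(factor(aa[lab == 0L], levels = PSSM_ALPHABET))
  fi <- as.vector(fi) / sum(fi)
  fr <- as.vector(fr) / sum(fr)
  undef <- fi == 0 | fr == 0
  ratio <- ifelse(undef, NA_real_, log2(fi / fr))
  data.frame(aa = PSSM_ALPHABET, freqInterface = fi, freqRest = fr,
             log2Ratio = ratio, undefined = undef)
}

## indices of the k nearest Calpha neighbours of each residue (target
## excluded); ties broken by smaller residue index.  Returns a list.
.caNeighbours <- function(chain, k) {
  res <- residueTable(chain)
  at <- atomTable(chain)
  caRows <- at[at$atomName == "CA", , drop = FALSE]
  ca <- matrix(NA_real_, nrow(res), 3)
  ca[caRows$residue, ] <- as.matrix(caRows[, c("x", "y", "z")])
  withCa <- which(!is.na(ca[, 1]))
  lapply(seq_len(nrow(res)), function(i) {
    if (is.na(ca[i, 1])) return(NULL)
    others <- setdiff(withCa, i)
    d <- sqrt((ca[others, 1] - ca[i, 1])^2 + (ca[others, 2] - ca[i, 2])^2 +
              (ca[others, 3] - ca[i, 3])^2)
    others[order(d, others)][seq_len(min(k, length(others)))]
  })
}

#' Count binding residues among spatial neighbours
#'
#' For each residue, the number of label-1 residues among its `k` nearest
#' Calpha neighbours (the residue itself excluded).  Binding residues
#' cluster in space, so this count separates the two classes sharply.
#'
#' @param chain a [ChainModel-class].
#' @param labels 0/1 integer vector, one per residue.
#' @param k neighbourhood size (default 18).
#' @return integer vector, one count per residue; `NA` for residues
#'   without a Calpha (excluded from the neighbourhood graph).
#' @export
neighborBindingCount <- function(chain, labels, k = 18L) {
  stopifnot(is(chain, "ChainModel"), length(labels) == nResidues(chain))
  nb <- .caNeighbours(chain, k)
  vapply(nb, function(idx) {
    if (is.null(idx)) NA_integer_ else sum(labels[idx] == 1L)
  }, integer(1))
}

#' Two-sample Kolmogorov-Smirnov comparison of an attribute
#'
#' Compares the distribution of a per-residue attribute (RASA, depth,
#' protrusion, conservation, ...) between binding and non-binding
#' residues.
#'
#' @param bindingValues,nonbindingValues numeric vectors.
#' @return list with `statistic` (D) and `p.value`.
#' @export
attributeDistributionTest <- function(bindingValues, nonbindingValues) {
  stopifnot(length(bindingValues) > 0, length(nonbindingValues) > 0)
  kt <- suppressWarnings(ks.test(bindingValues, nonbindingValues))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Bracketed attribute distribution summary
#'
#' Splits an attribute into brackets and reports, per bracket, the
#' fraction of binding and of non-binding residues falling in it (the
#' within-class percentages used for distribution plots).
#'
#' @param values numeric attribute vector.
#' @param labels 0/1 vector aligned with `values`.
#' @param breaks bracket edges as for [cut()].
#' @return `data.frame` with `bracket`, `fracBinding`, `fracNonbinding`.
#' @export
attributeBrackets <- function(values, labels, breaks) {
  b <- cut(values, breaks = breaks, include.lowest = TRUE)
  tb <- table(b, factor(labels, levels = c(0, 1)))
  data.frame(bracket = rownames(tb),
             fracBinding = tb[, "1"] / max(sum(tb[, "1"]), 1),
             fracNonbinding = tb[, "0"] / max(sum(tb[, "0"]), 1),
             row.names = NULL)
}

#' Export per-residue labels as TSV
#'
#' @param labeled a [LabeledChain-class].
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeLabelsTsv <- function(labeled, file) {
  res <- residueTable(labeled)
  out <- data.frame(chain = chainId(labeled), position = res$resKey,
                    aa = res$aa, label = bindingLabels(labeled))
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
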