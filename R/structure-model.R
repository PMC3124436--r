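## PDB ingestion: polymer chains -> ChainModel, HEM HETATM groups ->
## HemeGroup.  Record-level parsing is delegated to bio3d; this layer owns
## the altloc policy, hydrogen/water/HET filtering and residue grouping.

.threeToOne <- function(resName) {
  out <- AA_THREE_TO_ONE[resName]
  miss <- is.na(out)
  out[miss] <- AA_NONSTANDARD_MAP[resName[miss]]
  out[is.na(out)] <- "X"
  unname(out)
}

## altloc policy: within each (residue, atom name) keep the conformer with
## the highest occupancy; ties broken alphabetically by altloc id.
.resolveAltloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

.buildChainModel <- function(at, chain_id) {
  resKey <- paste0(at$resno, ifelse(is.na(at$insert), "", at$insert))
  ridx <- match(resKey, unique(resKey))  # file order
  aa <- .threeToOne(at$resid)
  atoms <- data.frame(
    residue = ridx,
    resKey = resKey,
    resName = at$resid,
    aa = aa,
    atomName = at$elety,
    element = toupper(trimws(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    isSidechain = !(at$elety %in% BACKBONE_ATOMS),
    stringsAsFactors = FALSE)
  ## residue-level consensus type: take the first atom's residue name
  first <- !duplicated(ridx)
  residues <- data.frame(
    resKey = resKey[first],
    resName = at$resid[first],
    aa = aa[first],
    hasCa = as.vector(tapply(at$elety == "CA", ridx, any)),
    stringsAsFactors = FALSE)
  atoms$aa <- residues$aa[ridx]
  new("ChainModel", chainId = chain_id, atoms = atoms, residues = residues)
}

#' Read a PDB file into chains and heme groups
#'
#' ATOM records (plus HETATM records of residues with a standard parent
#' type, e.g. selenomethionine) define the polymer; HETATM records with
#' residue name `HEM` define heme groups.  Hydrogens, waters and all other
#' HET groups are discarded.  Alternate locations are resolved to the
#' highest-occupancy conformer (ties by altloc id).
#'
#' @param file path to a PDB-format file.
#' @param structureId identifier stored on the heme groups (defaults to
#'   the file base name).
#' @return list with elements `chains` (list of [ChainModel-class]) and
#'   `hemes` (list of [HemeGroup-class]).
#' @examples
#' fx <- makeToyComplex(fixtureSpec(seed = 7))
#' f <- tempfile(fileext = ".pdb")
#' writeComplexPdb(fx$chain, fx$hemes, f)
#' st <- readStructure(f)
#' length(st$chains)
#' @export
readStructure <- function(file, structureId = sub("\\.pdb$", "", basename(file))) {
  pdb <- tryCatch(
    bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("not parseable as PDB: ", conditionMessage(e),
                             call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("not parseable as PDB: no atom records", call. = FALSE)
  at$elesy[is.na(at$elesy)] <- ""
  at <- at[!(toupper(trimws(at$elesy)) %in% c("H", "D")), , drop = FALSE]
  at$chain[is.na(at$chain)] <- " "

  isHeme <- at$type == "HETATM" & at$resid == "HEM"
  isPolymer <- at$type == "ATOM" |
    (at$type == "HETATM" & at$resid %in% names(AA_NONSTANDARD_MAP))

  hemes <- list()
  if (any(isHeme)) {
    ha <- at[isHeme, , drop = FALSE]
    hkey <- paste(ha$chain, ha$resno, ifelse(is.na(ha$insert), "", ha$insert))
    hemes <- lapply(split(seq_len(nrow(ha)), factor(hkey, levels = unique(hkey))),
      function(i) {
        new("HemeGroup", hetCode = "HEM",
            atoms = data.frame(atomName = ha$elety[i],
                               element = toupper(trimws(ha$elesy[i])),
                               x = ha$x[i], y = ha$y[i], z = ha$z[i],
                               stringsAsFactors = FALSE),
            structureId = structureId)
      })
    names(hemes) <- NULL
  }

  pa <- at[isPolymer, , drop = FALSE]
  if (nrow(pa) == 0L)
    stop("structure contains no polymer residues", call. = FALSE)
  pa <- .resolveAltloc(pa)
  ## restore file order after the altloc sort
  pa <- pa[order(pa$eleno), , drop = FALSE]
  chains <- lapply(split(seq_len(nrow(pa)), factor(pa$chain, levels = unique(pa$chain))),
                   function(i) .buildChainModel(pa[i, , drop = FALSE],
                                                chain_id = pa$chain[i[1]]))
  names(chains) <- vapply(chains, chainId, "")
  list(chains = chains, hemes = hemes)
}

#' Parse PDB-format text
#'
#' Convenience wrapper around [readStructure()] for in-memory text.
#'
#' @param text PDB records as a single string or character vector of lines.
#' @param structureId identifier stored on the heme groups.
#' @return as [readStructure()].
#' @export
parseStructure <- function(text, structureId = "structure") {
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeLines(paste(text, collapse = "\n"), f)
  readStructure(f, structureId = structureId)
}

#' One-letter sequence of a chain
#'
#' @param chain a [ChainModel-class].
#' @return string with one letter per residue (`X` for unknown types),
#'   in residue order.
#' @export
chainSequence <- function(chain) {
  stopifnot(is(chain, "ChainModel"))
  paste(residueTable(chain)$aa, collapse = "")
}

#' Write a chain (and optional hemes) back to PDB format
#'
#' @param chain a [ChainModel-class].
#' @param hemes list of [HemeGroup-class] (may be empty).
#' @param file output path.
#' @return invisibly, the file path.
#' @export
writeComplexPdb <- function(chain, hemes = list(), file) {
  stopifnot(is(chain, "ChainModel"))
  at <- atomTable(chain)
  fmt <- function(type, serial, name, resName, chainId, resno, x, y, z, elem) {
    name4 <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
    sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name4, resName, chainId, resno, x, y, z, 1, 0, elem)
  }
  resno <- suppressWarnings(as.integer(sub("[A-Za-z]$", "", at$resKey)))
  lines <- fmt("ATOM", seq_len(nrow(at)), at$atomName, at$resName,
               chainId(chain), resno, at$x, at$y, at$z, at$element)
  serial <- nrow(at)
  for (k in seq_along(hemes)) {
    ha <- atomTable(hemes[[k]])
    lines <- c(lines, fmt("HETATM", serial + seq_len(nrow(ha)), ha$atomName,
                          "HEM", chainId(chain), 900L + k, ha$x, ha$y, ha$z,
                          ha$element))
    serial <- serial + nrow(ha)
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}
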