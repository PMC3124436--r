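## Accessor generics; user code never reaches into slots directly.

#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("bindingLabels", function(x) standardGeneric("bindingLabels"))

#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))

#' @rdname accessors
#' @export
setGeneric("pssmSequence", function(x) standardGeneric("pssmSequence"))

#' @rdname accessors
#' @export
setGeneric("hetCode", function(x) standardGeneric("hetCode"))

#' Accessors for hemescan containers
#'
#' `chainId()`, `atomTable()`, `residueTable()` and `nResidues()` read a
#' [ChainModel-class] (or the chain inside a [LabeledChain-class]);
#' `bindingLabels()` reads the 0/1 label vector of a `LabeledChain`;
#' `pssmScores()` / `pssmSequence()` read a [PssmMatrix-class];
#' `hetCode()` and `atomTable()` read a [HemeGroup-class].
#'
#' @param x the object.
#' @return the corresponding slot content (copies, never references).
#' @name accessors
NULL

#' @rdname accessors
setMethod("chainId", "ChainModel", function(x) x@chainId)
#' @rdname accessors
setMethod("atomTable", "ChainModel", function(x) x@atoms)
#' @rdname accessors
setMethod("residueTable", "ChainModel", function(x) x@residues)
#' @rdname accessors
setMethod("nResidues", "ChainModel", function(x) nrow(x@residues))

#' @rdname accessors
setMethod("chainId", "LabeledChain", function(x) x@chain@chainId)
#' @rdname accessors
setMethod("atomTable", "LabeledChain", function(x) x@chain@atoms)
#' @rdname accessors
setMethod("residueTable", "LabeledChain", function(x) x@chain@residues)
#' @rdname accessors
setMethod("nResidues", "LabeledChain", function(x) nrow(x@chain@residues))
#' @rdname accessors
setMethod("bindingLabels", "LabeledChain", function(x) x@labels)

#' Extract the ChainModel from a LabeledChain
#' @param x a [LabeledChain-class].
#' @return the embedded [ChainModel-class].
#' @export
chainModel <- function(x) {
  stopifnot(is(x, "LabeledChain"))
  x@chain
}

#' @rdname accessors
setMethod("pssmScores", "PssmMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("pssmSequence", "PssmMatrix", function(x) x@sequence)

#' @rdname accessors
setMethod("hetCode", "HemeGroup", function(x) x@hetCode)
#' @rdname accessors
setMethod("atomTable", "HemeGroup", function(x) x@atoms)
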