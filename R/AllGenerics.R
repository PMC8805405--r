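# Accessor generics. Slot access outside the package goes through these.

#' @rdname accessors
#' @param x an object of one of the package's classes.
#' @export
setGeneric("chainRole", function(x) standardGeneric("chainRole"))

#' Accessors for the package's S4 classes
#'
#' `chainRole()` returns `"heavy"` or `"light"`; `residues()` the
#' amino-acid string; `cdrSpans()` the 3 x 2 matrix of half-open 0-based
#' CDR intervals; `nSnapshots()` / `nResidues()` the ensemble dimensions;
#' `atomRoster()` the per-atom table; `coords()` the coordinate array.
#'
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname accessors
#' @export
setGeneric("cdrSpans", function(x) standardGeneric("cdrSpans"))

#' @rdname accessors
#' @export
setGeneric("nSnapshots", function(x) standardGeneric("nSnapshots"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("atomRoster", function(x) standardGeneric("atomRoster"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

setMethod("chainRole", "ChainSequence", function(x) x@chainRole)
setMethod("chainRole", "CdrMap", function(x) x@chainRole)
setMethod("chainRole", "GermlineTemplate", function(x) x@chainRole)
setMethod("residues", "ChainSequence", function(x) x@residues)
setMethod("residues", "GermlineTemplate", function(x) x@residues)
setMethod("residues", "CdrSelection", function(x) x@residues)
setMethod("cdrSpans", "CdrMap", function(x) x@spans)
setMethod("nSnapshots", "StructureEnsemble", function(x) dim(x@coords)[1])
setMethod("nSnapshots", "ReferenceStats", function(x) x@nSnapshots)
setMethod("nResidues", "StructureEnsemble",
          function(x) length(unique(paste(x@atoms$chain, x@atoms$resi))))
setMethod("nResidues", "CdrSelection", function(x) nrow(x@residues))
setMethod("nResidues", "WrmsdResult", function(x) x@nResidues)
setMethod("atomRoster", "StructureEnsemble", function(x) x@atoms)
setMethod("coords", "StructureEnsemble", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("wrmsdValue", function(x) standardGeneric("wrmsdValue"))
setMethod("wrmsdValue", "WrmsdResult", function(x) x@wrmsd)

#' @rdname accessors
#' @export
setGeneric("rmsdPerResidueValues", function(x)
  standardGeneric("rmsdPerResidueValues"))
setMethod("rmsdPerResidueValues", "WrmsdResult", function(x) x@rmsdI)

#' @rdname accessors
#' @export
setGeneric("sasaValues", function(x) standardGeneric("sasaValues"))
setMethod("sasaValues", "SasaProfile", function(x) x@sI)

#' @rdname accessors
#' @export
setGeneric("sasaMean", function(x) standardGeneric("sasaMean"))
setMethod("sasaMean", "SasaProfile", function(x) x@sAvg)

#' @rdname accessors
#' @export
setGeneric("refDistances", function(x) standardGeneric("refDistances"))
setMethod("refDistances", "ReferenceStats", function(x) x@d0)

#' @rdname accessors
#' @export
setGeneric("refFluctuation", function(x) standardGeneric("refFluctuation"))
setMethod("refFluctuation", "ReferenceStats", function(x) x@rmsd0I)

setMethod("show", "ChainSequence", function(object) {
  cat(sprintf("ChainSequence '%s' (%s chain, %d aa)\n", object@id,
              object@chainRole, nchar(object@residues)))
})

setMethod("show", "CdrMap", function(object) {
  lab <- if (object@chainRole == "heavy") "H" else "L"
  sp <- object@spans
  cat(sprintf("CdrMap (%s chain): %s\n", object@chainRole,
              paste(sprintf("%s%d=[%d,%d)", lab, 1:3, sp[, 1], sp[, 2]),
                    collapse = " ")))
})

setMethod("show", "GermlineTemplate", function(object) {
  cat(sprintf("GermlineTemplate %s (%s segment, %s chain, %d aa)\n",
              object@geneName, object@segment, object@chainRole,
              nchar(object@residues)))
})

setMethod("show", "HumanizedCandidate", function(object) {
  cat(sprintf("HumanizedCandidate %s: VL %d aa, VH %d aa\n",
              object@candidateId, nchar(object@vl), nchar(object@vh)))
})

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d snapshot(s), %d residue(s), %d atom(s)\n",
              nSnapshots(object), nResidues(object), nrow(object@atoms)))
})

setMethod("show", "ReferenceStats", function(object) {
  cat(sprintf(
    "ReferenceStats: N=%d residues over %d snapshot(s); mean fluctuation %.3f A\n",
    nrow(object@d0), object@nSnapshots, object@rmsd0Avg))
})

setMethod("show", "WrmsdResult", function(object) {
  cat(sprintf("WrmsdResult: wRMSD = %.4f A over %d CDR residues\n",
              object@wrmsd, object@nResidues))
})

setMethod("show", "CorrelationFit", function(object) {
  cat(sprintf(
    "CorrelationFit: log10(affinity) = %.4f * wRMSD + %.4f (R^2 = %.4f, n = %d)\n",
    object@slope, object@intercept, object@rSquared, object@nPoints))
})

setMethod("show", "SasaProfile", function(object) {
  cat(sprintf("SasaProfile: %d residues, mean SASA %.2f A^2\n",
              length(object@sI), object@sAvg))
})
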