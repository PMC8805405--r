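#' @import methods
NULL

AA_ALPHABET1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' ChainSequence: an antibody variable-domain amino-acid sequence
#'
#' Holds one variable-domain chain (heavy or light) as a one-letter
#' amino-acid string together with its role. Validity enforces the 20
#' standard residue codes and a length plausible for an immunoglobulin
#' variable domain (90--150 residues).
#'
#' @slot id character label for the chain.
#' @slot chainRole `"heavy"` or `"light"`.
#' @slot residues one-letter amino-acid string.
#'
#' @seealso [chainSequence()], [annotateCdrs()]
#' @exportClass ChainSequence
setClass("ChainSequence",
  representation(id = "character", chainRole = "character",
                 residues = "character"))

setValidity("ChainSequence", function(object) {
  msg <- character()
  if (length(object@chainRole) != 1L ||
      !object@chainRole %in% c("heavy", "light"))
    msg <- c(msg, "chainRole must be 'heavy' or 'light'")
  if (length(object@residues) != 1L)
    msg <- c(msg, "residues must be a single string")
  else {
    chars <- strsplit(object@residues, "")[[1]]
    if (!all(chars %in% AA_ALPHABET1))
      msg <- c(msg, sprintf("non-standard residue code(s): %s",
                            paste(unique(setdiff(chars, AA_ALPHABET1)),
                                  collapse = ", ")))
    n <- length(chars)
    if (n < 90L || n > 150L)
      msg <- c(msg, sprintf(
        "sequence length %d outside the variable-domain range [90, 150]", n))
  }
  if (length(msg)) msg else TRUE
})

#' CdrMap: CDR index spans of one variable-domain chain
#'
#' Three half-open, 0-based index intervals labelling CDR1, CDR2 and CDR3
#' of a heavy or light chain. Spans are disjoint, ordered and non-empty.
#'
#' @slot spans 3 x 2 integer matrix, rows `CDR1`..`CDR3`, columns
#'   `start`, `end` (half-open, 0-based).
#' @slot chainRole `"heavy"` or `"light"`.
#'
#' @seealso [annotateCdrs()], [cdrMap()]
#' @exportClass CdrMap
setClass("CdrMap",
  representation(spans = "matrix", chainRole = "character"))

setValidity("CdrMap", function(object) {
  sp <- object@spans
  msg <- character()
  if (!is.numeric(sp) || !identical(dim(sp), c(3L, 2L)))
    msg <- c(msg, "spans must be a 3 x 2 matrix")
  else {
    if (any(sp != as.integer(sp)) || any(sp < 0))
      msg <- c(msg, "span bounds must be non-negative integers (0-based)")
    if (any(sp[, 2] <= sp[, 1]))
      msg <- c(msg, "each CDR span must be non-empty (end > start)")
    if (any(diff(as.vector(t(sp))) < 0))
      msg <- c(msg, "spans must be ordered and disjoint")
  }
  if (length(object@chainRole) != 1L ||
      !object@chainRole %in% c("heavy", "light"))
    msg <- c(msg, "chainRole must be 'heavy' or 'light'")
  if (length(msg)) msg else TRUE
})

#' GermlineTemplate: a human germline V or J gene segment
#'
#' @slot geneName gene name, e.g. `"IGKV6-21*01"`.
#' @slot segment `"V"` or `"J"`.
#' @slot chainRole `"heavy"` or `"light"`.
#' @slot residues amino-acid string (V segments cover FR1 through the
#'   start of CDR3; J segments cover the CDR3 tail plus FR4).
#'
#' @seealso [readGermlineFasta()], [selectTemplates()], [graftChain()]
#' @exportClass GermlineTemplate
setClass("GermlineTemplate",
  representation(geneName = "character", segment = "character",
                 chainRole = "character", residues = "character"))

setValidity("GermlineTemplate", function(object) {
  msg <- character()
  if (!object@segment %in% c("V", "J"))
    msg <- c(msg, "segment must be 'V' or 'J'")
  if (!object@chainRole %in% c("heavy", "light"))
    msg <- c(msg, "chainRole must be 'heavy' or 'light'")
  if (length(object@residues) != 1L || nchar(object@residues) == 0L)
    msg <- c(msg, "residues must be a non-empty string")
  else if (!all(strsplit(object@residues, "")[[1]] %in% AA_ALPHABET1))
    msg <- c(msg, "residues contain non-standard codes")
  if (length(msg)) msg else TRUE
})

#' GraftDesign: a named set of framework back mutations
#'
#' A graft design is identified by a short label (conventionally a single
#' letter, upper case for VL designs, lower case for VH) and carries the
#' framework positions to revert to the murine residue after grafting.
#'
#' @slot designId design label, e.g. `"A"`.
#' @slot backMutations data.frame with columns `pos` (0-based index into
#'   the grafted chain) and `residue` (one-letter code to substitute).
#'
#' @seealso [graftChain()], [readDesignsJson()]
#' @exportClass GraftDesign
setClass("GraftDesign",
  representation(designId = "character", backMutations = "data.frame"))

setValidity("GraftDesign", function(object) {
  bm <- object@backMutations
  msg <- character()
  if (!all(c("pos", "residue") %in% names(bm)))
    msg <- c(msg, "backMutations needs columns 'pos' and 'residue'")
  else {
    if (nrow(bm) && (any(bm$pos < 0) || any(bm$pos != as.integer(bm$pos))))
      msg <- c(msg, "back-mutation positions must be non-negative integers")
    if (nrow(bm) && !all(bm$residue %in% AA_ALPHABET1))
      msg <- c(msg, "back-mutation residues must be standard one-letter codes")
  }
  if (length(msg)) msg else TRUE
})

#' HumanizedCandidate: a paired VL + VH humanized design
#'
#' @slot candidateId candidate label, e.g. `"(A + a)"`.
#' @slot vl grafted light-chain sequence (character).
#' @slot vh grafted heavy-chain sequence (character).
#' @slot vlCdrs [CdrMap] of the grafted light chain.
#' @slot vhCdrs [CdrMap] of the grafted heavy chain.
#' @slot provenance list with the VL/VH design ids and template gene names.
#'
#' @seealso [enumerateCandidates()]
#' @exportClass HumanizedCandidate
setClass("HumanizedCandidate",
  representation(candidateId = "character", vl = "character",
                 vh = "character", vlCdrs = "CdrMap", vhCdrs = "CdrMap",
                 provenance = "list"))

#' StructureEnsemble: ordered conformational snapshots of one molecule
#'
#' An ensemble holds a fixed atom roster (identical across snapshots) and a
#' snapshots x atoms x 3 coordinate array in Angstrom. Multi-model PDB
#' files and plain coordinate tables are read into this container.
#'
#' @slot atoms data.frame with one row per atom: `chain`, `resi` (residue
#'   identifier as character, insertion codes appended verbatim), `resn`,
#'   `atom` (atom name), `element`.
#' @slot coords numeric array, `dim = c(nSnapshots, nAtoms, 3)`.
#'
#' @seealso [readEnsemble()], [extractCdrCalpha()]
#' @exportClass StructureEnsemble
setClass("StructureEnsemble",
  representation(atoms = "data.frame", coords = "array"))

setValidity("StructureEnsemble", function(object) {
  msg <- character()
  at <- object@atoms
  need <- c("chain", "resi", "resn", "atom", "element")
  if (!all(need %in% names(at)))
    msg <- c(msg, sprintf("atoms must have columns %s",
                          paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be a snapshots x atoms x 3 array")
  else {
    if (d[1] < 1L) msg <- c(msg, "ensemble must contain at least one snapshot")
    if (all(need %in% names(at)) && d[2] != nrow(at))
      msg <- c(msg, "coords atom dimension does not match the atom roster")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    # every residue has exactly one Calpha
    if (all(need %in% names(at))) {
      key <- paste(at$chain, at$resi)
      nca <- tapply(at$atom == "CA", key, sum)
      if (any(nca != 1L))
        msg <- c(msg, sprintf("residue %s has %d CA atoms (expected 1)",
                              names(nca)[which(nca != 1L)[1]],
                              nca[which(nca != 1L)[1]]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' CdrSelection: the ordered CDR residue set of an ensemble
#'
#' Names the N CDR residues (union of the six CDRs, light chain first,
#' then heavy) over which the per-residue interatomic RMSD is defined.
#'
#' @slot residues data.frame with columns `chain` and `resi`, in selection
#'   order.
#'
#' @seealso [cdrSelection()], [extractCdrCalpha()]
#' @exportClass CdrSelection
setClass("CdrSelection", representation(residues = "data.frame"))

setValidity("CdrSelection", function(object) {
  r <- object@residues
  msg <- character()
  if (!all(c("chain", "resi") %in% names(r)))
    msg <- c(msg, "residues must have columns 'chain' and 'resi'")
  else {
    if (nrow(r) < 2L)
      msg <- c(msg, "a CDR selection needs at least 2 residues")
    if (anyDuplicated(paste(r$chain, r$resi)))
      msg <- c(msg, "selected residues must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' SasaProfile: mean per-residue solvent accessibility of the CDR set
#'
#' @slot sI named numeric, mean SASA per CDR residue in Angstrom^2,
#'   averaged over snapshots.
#' @slot sAvg arithmetic mean of `sI` over the CDR residues.
#'
#' @seealso [residueSasaProfile()], [cdrWeights()]
#' @exportClass SasaProfile
setClass("SasaProfile", representation(sI = "numeric", sAvg = "numeric"))

setValidity("SasaProfile", function(object) {
  msg <- character()
  if (any(object@sI < 0)) msg <- c(msg, "per-residue SASA must be >= 0")
  if (length(object@sI) &&
      abs(object@sAvg - mean(object@sI)) > 1e-8 * max(1, object@sAvg))
    msg <- c(msg, "sAvg must equal mean(sI)")
  if (length(msg)) msg else TRUE
})

#' ReferenceStats: murine-ensemble distance statistics
#'
#' Statistics of the murine (reference) CDR ensemble: the time-averaged
#' Calpha--Calpha distance matrix and the per-residue fluctuation about it,
#' which supplies the movability weight denominator.
#'
#' @slot d0 N x N mean distance matrix (Angstrom), zero diagonal.
#' @slot rmsd0I per-residue fluctuation of the reference ensemble about
#'   `d0` (Angstrom).
#' @slot rmsd0Avg arithmetic mean of `rmsd0I`.
#' @slot nSnapshots number of reference snapshots used.
#'
#' @seealso [referenceStats()], [rmsdPerResidue()], [cdrWeights()]
#' @exportClass ReferenceStats
setClass("ReferenceStats",
  representation(d0 = "matrix", rmsd0I = "numeric", rmsd0Avg = "numeric",
                 nSnapshots = "integer"))

setValidity("ReferenceStats", function(object) {
  msg <- character()
  d0 <- object@d0
  if (nrow(d0) != ncol(d0)) msg <- c(msg, "d0 must be square")
  else {
    if (max(abs(d0 - t(d0))) > 1e-9) msg <- c(msg, "d0 must be symmetric")
    if (any(abs(diag(d0)) > 1e-12)) msg <- c(msg, "d0 diagonal must be zero")
    if (any(d0 < 0)) msg <- c(msg, "d0 must be non-negative")
    if (length(object@rmsd0I) != nrow(d0))
      msg <- c(msg, "rmsd0I length must match d0 dimension")
  }
  if (any(object@rmsd0I < 0)) msg <- c(msg, "rmsd0I must be >= 0")
  if (length(object@rmsd0I) &&
      abs(object@rmsd0Avg - mean(object@rmsd0I)) >
        1e-9 * max(1, object@rmsd0Avg))
    msg <- c(msg, "rmsd0Avg must equal mean(rmsd0I)")
  if (length(msg)) msg else TRUE
})

#' WrmsdResult: weighted interatomic RMSD of one candidate
#'
#' @slot rmsdI per-residue interatomic RMSD (Angstrom), length N.
#' @slot wAcc per-residue accessibility weight.
#' @slot wMov per-residue movability weight.
#' @slot wrmsd scalar weighted score (Angstrom).
#' @slot nPairs number of distance partners per residue (N - 1).
#' @slot nResidues N.
#'
#' @seealso [wrmsd()], [wrmsdScore()]
#' @exportClass WrmsdResult
setClass("WrmsdResult",
  representation(rmsdI = "numeric", wAcc = "numeric", wMov = "numeric",
                 wrmsd = "numeric", nPairs = "integer",
                 nResidues = "integer"))

setValidity("WrmsdResult", function(object) {
  msg <- character()
  n <- object@nResidues
  if (length(object@rmsdI) != n || length(object@wAcc) != n ||
      length(object@wMov) != n)
    msg <- c(msg, "rmsdI, wAcc, wMov must all have length nResidues")
  if (any(object@rmsdI < 0)) msg <- c(msg, "rmsdI must be >= 0")
  if (any(object@wAcc <= 0) || any(object@wMov <= 0))
    msg <- c(msg, "weights must be > 0")
  expect <- sum(object@wAcc * object@wMov * object@rmsdI) / n
  if (abs(object@wrmsd - expect) > 1e-9 * max(1, expect))
    msg <- c(msg, "wrmsd must equal sum(wAcc * wMov * rmsdI) / N")
  if (length(msg)) msg else TRUE
})

#' CorrelationFit: log-linear affinity regression
#'
#' Ordinary least-squares fit of log10(affinity) on the wRMSD score.
#'
#' @slot slope regression slope (per Angstrom).
#' @slot intercept regression intercept (log10 units of the affinity).
#' @slot rSquared squared Pearson correlation, in `[0, 1]`.
#' @slot nPoints number of (uncensored) points used.
#' @slot logBase logarithm base (10).
#'
#' @seealso [fitLogAffinity()], [predictAffinity()]
#' @exportClass CorrelationFit
setClass("CorrelationFit",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", nPoints = "integer",
                 logBase = "numeric"))

setValidity("CorrelationFit", function(object) {
  msg <- character()
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (object@nPoints < 2L) msg <- c(msg, "nPoints must be >= 2")
  if (length(msg)) msg else TRUE
})

#' EnsembleSpec: recipe for a synthetic structure ensemble
#'
#' Describes a synthetic Calpha chain (3.8 Angstrom virtual bonds) and the
#' stochastic model used to emulate a conformational ensemble: independent
#' per-residue Gaussian jitter about a base conformation, plus an optional
#' systematic displacement of selected residues.
#'
#' @slot nResidues number of residues.
#' @slot nSnapshots number of snapshots to generate.
#' @slot baseGeometry `"helix"`, `"extended"` or `"random-walk"`.
#' @slot jitterSd per-residue Gaussian standard deviation (Angstrom);
#'   length 1 (recycled) or `nResidues`.
#' @slot displacement numeric matrix with columns `resi` (1-based residue
#'   index), `dx`, `dy`, `dz`; zero rows for no displacement.
#' @slot seed integer seed fixing all randomness.
#'
#' @seealso [ensembleSpec()], [makeReferenceEnsemble()]
#' @exportClass EnsembleSpec
setClass("EnsembleSpec",
  representation(nResidues = "integer", nSnapshots = "integer",
                 baseGeometry = "character", jitterSd = "numeric",
                 displacement = "matrix", seed = "integer"))

setValidity("EnsembleSpec", function(object) {
  msg <- character()
  if (object@nResidues < 2L) msg <- c(msg, "nResidues must be >= 2")
  if (object@nSnapshots < 1L) msg <- c(msg, "nSnapshots must be >= 1")
  if (!object@baseGeometry %in% c("helix", "extended", "random-walk"))
    msg <- c(msg, "baseGeometry must be helix, extended or random-walk")
  if (any(object@jitterSd < 0)) msg <- c(msg, "jitterSd must be >= 0")
  if (!length(object@jitterSd) %in% c(1L, object@nResidues))
    msg <- c(msg, "jitterSd must have length 1 or nResidues")
  if (ncol(object@displacement) != 4L)
    msg <- c(msg, "displacement must have columns resi, dx, dy, dz")
  else if (nrow(object@displacement) &&
           (any(object@displacement[, 1] < 1) ||
            any(object@displacement[, 1] > object@nResidues)))
    msg <- c(msg, "displacement residue index out of range")
  if (length(msg)) msg else TRUE
})
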