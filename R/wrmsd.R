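#' Calpha-Calpha distance matrix of one snapshot
#'
#' @param coords numeric `N x 3` matrix of Calpha coordinates (Angstrom).
#' @return symmetric `N x N` matrix of Euclidean distances, zero diagonal.
#' @export
distanceMatrix <- function(coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (nrow(coords) < 2L)
    stop("need at least 2 residues for a distance matrix", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must be finite", call. = FALSE)
  as.matrix(stats::dist(coords))
}

# snapshots x N x N distance array
distanceArray <- function(tensor) {
  nT <- dim(tensor)[1]
  N <- dim(tensor)[2]
  D <- array(NA_real_, dim = c(nT, N, N))
  for (t in seq_len(nT)) D[t, , ] <- distanceMatrix(tensor[t, , ])
  D
}

# per-snapshot, per-residue deviation RMS against a fixed reference matrix:
# r_i(t) = sqrt(sum_{j != i} (d_ij(t) - d0_ij)^2 / (N - 1))
perSnapshotDeviation <- function(D, d0) {
  nT <- dim(D)[1]
  N <- dim(D)[2]
  out <- matrix(NA_real_, nT, N)
  for (t in seq_len(nT)) {
    dev2 <- (D[t, , ] - d0)^2
    diag(dev2) <- 0
    out[t, ] <- sqrt(rowSums(dev2) / (N - 1))
  }
  out
}

#' Distance statistics of the murine reference ensemble
#'
#' `d0` is the mean over snapshots of each snapshot's Calpha-Calpha
#' distance matrix. The per-residue fluctuation `rmsd0_i` applies the
#' interatomic-RMSD formula to the reference ensemble against its own
#' `d0` (per-snapshot deviation, averaged over snapshots); its arithmetic
#' mean `rmsd0_avg` is the movability-weight denominator. A single-snapshot
#' reference is valid but has zero fluctuation everywhere; movability
#' weights then degenerate and [cdrWeights()] substitutes uniform weights
#' with a warning.
#'
#' @param tensor reference Calpha coordinates, `snapshots x N x 3`.
#' @return a [ReferenceStats-class].
#' @export
referenceStats <- function(tensor) {
  if (length(dim(tensor)) == 2L)
    tensor <- array(tensor, dim = c(1L, dim(tensor)))
  nT <- dim(tensor)[1]
  N <- dim(tensor)[2]
  if (nT < 1L) stop("need at least one snapshot", call. = FALSE)
  D <- distanceArray(tensor)
  d0 <- apply(D, c(2, 3), mean)
  d0 <- (d0 + t(d0)) / 2
  diag(d0) <- 0
  rmsd0 <- colMeans(perSnapshotDeviation(D, d0))
  new("ReferenceStats", d0 = d0, rmsd0I = rmsd0, rmsd0Avg = mean(rmsd0),
      nSnapshots = as.integer(nT))
}

#' Per-residue interatomic RMSD against the reference
#'
#' For each candidate snapshot `t` and CDR residue `i`,
#' `r_i(t) = sqrt(sum_{j != i} (d_ij(t) - d0_ij)^2 / n)` with `n = N - 1`
#' distance partners. The default (`"snapshot-mean"`) reports the mean of
#' `r_i(t)` over snapshots; `"pooled"` instead takes the RMS over pooled
#' squared deviations, `sqrt(mean_t r_i(t)^2)`. Both reduce to the same
#' value for a single snapshot. No superposition is performed: the metric
#' is built from internal distances only and is rigid-body invariant.
#'
#' @param tensor candidate Calpha coordinates, `snapshots x N x 3`; `N`
#'   must equal the reference's (CDRs are grafted verbatim, so lengths
#'   match; a mismatch is an error, never realigned).
#' @param ref a [ReferenceStats-class].
#' @param method `"snapshot-mean"` (default) or `"pooled"`.
#' @return numeric vector of per-residue RMSD (Angstrom), length `N`.
#' @export
rmsdPerResidue <- function(tensor, ref,
                           method = c("snapshot-mean", "pooled")) {
  method <- match.arg(method)
  if (length(dim(tensor)) == 2L)
    tensor <- array(tensor, dim = c(1L, dim(tensor)))
  N <- dim(tensor)[2]
  if (N != nrow(ref@d0))
    stop("candidate has ", N, " CDR residues but the reference has ",
         nrow(ref@d0), "; residue correspondence must be one-to-one",
         call. = FALSE)
  dev <- perSnapshotDeviation(distanceArray(tensor), ref@d0)
  if (method == "snapshot-mean") colMeans(dev) else sqrt(colMeans(dev^2))
}

#' Accessibility and movability weights
#'
#' `w_acc_i = 1 / (S_i / S_avg) = S_avg / S_i` from the SASA profile and
#' `w_mov_i = 1 / (rmsd0_i / rmsd0_avg) = rmsd0_avg / rmsd0_i` from the
#' reference fluctuation: solvent-exposed residues (plausible antigen
#' binders) are up-weighted, intrinsically flexible residues are
#' down-weighted. Degenerate inputs are floored with a warning: a fully
#' buried residue's `S_i` at 1 Angstrom^2, a rigid residue's `rmsd0_i` at
#' 1e-6 Angstrom; if the reference has no fluctuation at all (static or
#' single-snapshot ensemble) uniform movability weights are substituted.
#' With `sasa = NULL` uniform accessibility weights are used.
#'
#' @param ref a [ReferenceStats-class].
#' @param sasa a [SasaProfile-class], or `NULL` for uniform weights.
#' @return list with numeric vectors `wAcc` and `wMov`.
#' @export
cdrWeights <- function(ref, sasa = NULL) {
  N <- length(ref@rmsd0I)
  if (is.null(sasa)) {
    wAcc <- rep(1, N)
  } else {
    sI <- sasa@sI
    if (length(sI) != N)
      stop("SASA profile length does not match the reference", call. = FALSE)
    if (any(sI < 1)) {
      warning("buried residue(s) with SASA < 1 A^2 floored at 1 A^2 ",
              "for the accessibility weight")
      sI <- pmax(sI, 1)
    }
    wAcc <- sasa@sAvg / sI
  }
  r0 <- ref@rmsd0I
  if (all(r0 == 0)) {
    warning("reference ensemble has zero fluctuation (static or single ",
            "snapshot); movability weights are undefined and uniform ",
            "weights were substituted")
    wMov <- rep(1, N)
  } else {
    if (any(r0 < 1e-6)) {
      warning("rigid residue(s) with rmsd0 < 1e-6 A floored at 1e-6 A ",
              "for the movability weight")
      r0 <- pmax(r0, 1e-6)
    }
    wMov <- ref@rmsd0Avg / r0
  }
  list(wAcc = wAcc, wMov = wMov)
}

#' Scalar weighted score
#'
#' `wRMSD = sum_i(w_acc_i * w_mov_i * RMSD_i) / N`.
#'
#' @param rmsdI per-residue RMSD vector.
#' @param wAcc,wMov weight vectors of the same length.
#' @return scalar (Angstrom).
#' @export
wrmsdScore <- function(rmsdI, wAcc, wMov) {
  if (length(wAcc) != length(rmsdI) || length(wMov) != length(rmsdI))
    stop("rmsdI, wAcc and wMov must have equal length", call. = FALSE)
  sum(wAcc * wMov * rmsdI) / length(rmsdI)
}

#' Weighted interatomic RMSD of a candidate ensemble
#'
#' End-to-end scoring: reference statistics from the murine ensemble,
#' per-residue interatomic RMSD of the candidate against them, weights,
#' and the scalar score. Inputs may be [StructureEnsemble-class] objects
#' (with a shared [CdrSelection-class]) or raw `snapshots x N x 3` Calpha
#' tensors. The SASA profile, when given, is computed from the murine
#' reference so all candidates share identical weights.
#'
#' @param reference murine [StructureEnsemble-class], Calpha tensor, or a
#'   precomputed [ReferenceStats-class].
#' @param candidate candidate [StructureEnsemble-class] or Calpha tensor.
#' @param selection [CdrSelection-class]; required when ensembles are
#'   given.
#' @param sasa optional [SasaProfile-class] (uniform accessibility weights
#'   when `NULL`).
#' @param method snapshot treatment, see [rmsdPerResidue()].
#' @return a [WrmsdResult-class].
#' @export
wrmsd <- function(reference, candidate, selection = NULL, sasa = NULL,
                  method = c("snapshot-mean", "pooled")) {
  method <- match.arg(method)
  asTensor <- function(x) {
    if (is(x, "StructureEnsemble")) {
      if (is.null(selection))
        stop("a CdrSelection is required with ensemble input", call. = FALSE)
      extractCdrCalpha(x, selection)
    } else x
  }
  ref <- if (is(reference, "ReferenceStats")) reference
         else referenceStats(asTensor(reference))
  rmsdI <- rmsdPerResidue(asTensor(candidate), ref, method = method)
  w <- cdrWeights(ref, sasa)
  new("WrmsdResult", rmsdI = rmsdI, wAcc = w$wAcc, wMov = w$wMov,
      wrmsd = wrmsdScore(rmsdI, w$wAcc, w$wMov),
      nPairs = as.integer(nrow(ref@d0) - 1L),
      nResidues = as.integer(nrow(ref@d0)))
}

#' Score a batch of candidate ensembles
#'
#' @param reference murine [StructureEnsemble-class] or Calpha tensor.
#' @param candidates named list of candidate ensembles/tensors.
#' @param selection shared [CdrSelection-class] (for ensemble input).
#' @param sasa optional [SasaProfile-class].
#' @param method see [rmsdPerResidue()].
#' @return data.frame `candidate_id`, `wrmsd`, `similarity_ranking`,
#'   sorted ascending by score (see [rankByWrmsd()]).
#' @export
scoreCandidates <- function(reference, candidates, selection = NULL,
                            sasa = NULL,
                            method = c("snapshot-mean", "pooled")) {
  method <- match.arg(method)
  ref <- if (is(reference, "ReferenceStats")) reference
         else referenceStats(if (is(reference, "StructureEnsemble"))
           extractCdrCalpha(reference, selection) else reference)
  ids <- names(candidates)
  if (is.null(ids)) ids <- sprintf("candidate_%d", seq_along(candidates))
  scores <- vapply(candidates, function(cand)
    wrmsdValue(wrmsd(ref, cand, selection = selection, sasa = sasa,
                     method = method)), numeric(1))
  rankByWrmsd(data.frame(candidate_id = ids, wrmsd = unname(scores),
                         stringsAsFactors = FALSE))
}
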