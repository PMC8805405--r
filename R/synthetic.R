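# Synthetic ensembles and affinity panels with known ground truth.
# Snapshots are per-residue Gaussian jitter about a fixed base chain
# (3.8 A virtual Calpha bonds), optionally with a systematic displacement
# of selected residues; affinities follow a log-linear relation in the
# wRMSD score plus Gaussian noise on the log scale. All randomness comes
# from R's default Mersenne-Twister generator under the recorded seed.

#' Construct an EnsembleSpec
#'
#' @param nResidues number of residues (>= 2).
#' @param nSnapshots number of snapshots (>= 1).
#' @param baseGeometry `"helix"` (ideal Calpha helix: radius 2.3 A, rise
#'   1.5 A, 100 degrees/residue), `"extended"` (3.8 A steps along x) or
#'   `"random-walk"` (3.8 A steps in seeded random directions).
#' @param jitterSd per-residue Gaussian sd in Angstrom (length 1 or
#'   `nResidues`).
#' @param displacement matrix/data.frame with columns `resi` (1-based),
#'   `dx`, `dy`, `dz`, or `NULL`.
#' @param seed integer seed fixing all randomness.
#' @return an [EnsembleSpec-class].
#' @export
ensembleSpec <- function(nResidues, nSnapshots, baseGeometry = "helix",
                         jitterSd = 0.3, displacement = NULL, seed = 1L) {
  disp <- displacementMatrix(displacement)
  new("EnsembleSpec", nResidues = as.integer(nResidues),
      nSnapshots = as.integer(nSnapshots),
      baseGeometry = baseGeometry, jitterSd = as.numeric(jitterSd),
      displacement = disp, seed = as.integer(seed))
}

displacementMatrix <- function(displacement) {
  if (is.null(displacement) || !length(displacement))
    return(matrix(numeric(), 0L, 4L,
                  dimnames = list(NULL, c("resi", "dx", "dy", "dz"))))
  m <- as.matrix(displacement)
  if (ncol(m) != 4L)
    stop("displacement needs columns resi, dx, dy, dz", call. = FALSE)
  colnames(m) <- c("resi", "dx", "dy", "dz")
  m
}

baseCoordinates <- function(spec) {
  n <- spec@nResidues
  base <- switch(spec@baseGeometry,
    helix = {
      theta <- (seq_len(n) - 1L) * 100 * pi / 180
      cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (seq_len(n) - 1L))
    },
    extended = cbind(3.8 * (seq_len(n) - 1L), 0, 0),
    `random-walk` = {
      set.seed(spec@seed + 101L)
      dirs <- matrix(stats::rnorm(3 * (n - 1L)), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      rbind(c(0, 0, 0), apply(dirs * 3.8, 2, cumsum))
    })
  if (nrow(spec@displacement)) {
    idx <- spec@displacement[, "resi"]
    if (any(idx < 1) || any(idx > n))
      stop("displacement residue index out of range", call. = FALSE)
    base[idx, ] <- base[idx, , drop = FALSE] +
      spec@displacement[, c("dx", "dy", "dz"), drop = FALSE]
  }
  base
}

# idealized backbone offsets for dummy all-atom residues (no chemistry,
# just four atoms per residue so SASA has something to integrate)
DUMMY_ATOM_OFFSETS <- rbind(
  N = c(-1.20, 0.80, 0.00),
  CA = c(0.00, 0.00, 0.00),
  C = c(1.20, 0.80, 0.00),
  O = c(2.00, 1.60, 0.40))

#' Generate a synthetic reference ensemble
#'
#' Snapshot `t` places residue `i` at `base_i + N(0, jitterSd_i^2)` per
#' axis; the same seed always reproduces the ensemble bit for bit. With
#' `allAtom = TRUE`, each residue carries dummy backbone atoms (N, CA, C,
#' O at idealized offsets, moving rigidly with the residue) so SASA can
#' be computed; otherwise the ensemble is Calpha-only.
#'
#' @param spec an [EnsembleSpec-class].
#' @param allAtom logical.
#' @param chain chain id for the roster.
#' @return a [StructureEnsemble-class].
#' @examples
#' sp <- ensembleSpec(8, 5, jitterSd = 0.2, seed = 42)
#' makeReferenceEnsemble(sp)
#' @export
makeReferenceEnsemble <- function(spec, allAtom = FALSE, chain = "L") {
  n <- spec@nResidues
  nT <- spec@nSnapshots
  base <- baseCoordinates(spec)
  sd <- rep(spec@jitterSd, length.out = n)
  set.seed(spec@seed)
  jitter <- array(stats::rnorm(nT * n * 3, sd = rep(sd, each = nT)),
                  dim = c(nT, n, 3))
  ca <- jitter + rep(1, nT) %o% base   # residue positions per snapshot
  if (!allAtom) {
    atoms <- data.frame(chain = chain, resi = as.character(seq_len(n)),
                        resn = "GLY", atom = "CA", element = "C",
                        stringsAsFactors = FALSE)
    return(structureEnsemble(atoms, ca))
  }
  nm <- rownames(DUMMY_ATOM_OFFSETS)
  atoms <- data.frame(
    chain = chain, resi = as.character(rep(seq_len(n), each = 4L)),
    resn = "GLY", atom = rep(nm, n),
    element = substr(rep(nm, n), 1L, 1L), stringsAsFactors = FALSE)
  coords <- array(NA_real_, dim = c(nT, 4L * n, 3L))
  for (i in seq_len(n)) for (a in 1:4)
    coords[, (i - 1L) * 4L + a, ] <-
      ca[, i, ] + rep(1, nT) %o% DUMMY_ATOM_OFFSETS[a, ]
  structureEnsemble(atoms, coords)
}

#' Generate a candidate ensemble with a systematic CDR displacement
#'
#' The base conformation of `referenceSpec` is shifted by `displacement`
#' (emulating a humanized candidate whose CDR geometry deviates from the
#' murine parent) and a fresh ensemble is jittered about it under `seed`.
#'
#' @param referenceSpec the reference [EnsembleSpec-class].
#' @param displacement matrix/data.frame with columns `resi`, `dx`, `dy`,
#'   `dz` (1-based residue indices; out of range is an error).
#' @param seed seed for the candidate's jitter.
#' @param allAtom,chain as in [makeReferenceEnsemble()].
#' @return a [StructureEnsemble-class].
#' @export
makeCandidateEnsemble <- function(referenceSpec, displacement = NULL,
                                  seed = referenceSpec@seed + 1L,
                                  allAtom = FALSE, chain = "L") {
  disp <- displacementMatrix(displacement)
  if (nrow(disp) && (any(disp[, "resi"] < 1) ||
                     any(disp[, "resi"] > referenceSpec@nResidues)))
    stop("displacement residue index out of range", call. = FALSE)
  spec <- new("EnsembleSpec", nResidues = referenceSpec@nResidues,
              nSnapshots = referenceSpec@nSnapshots,
              baseGeometry = referenceSpec@baseGeometry,
              jitterSd = referenceSpec@jitterSd,
              displacement = rbind(referenceSpec@displacement, disp),
              seed = as.integer(seed))
  # random-walk bases must come from the reference seed so that the
  # candidate is the same chain, displaced
  if (spec@baseGeometry == "random-walk") {
    base <- baseCoordinates(referenceSpec)
    if (nrow(disp)) {
      idx <- disp[, "resi"]
      base[idx, ] <- base[idx, , drop = FALSE] +
        disp[, c("dx", "dy", "dz"), drop = FALSE]
    }
    n <- spec@nResidues
    nT <- spec@nSnapshots
    sd <- rep(spec@jitterSd, length.out = n)
    set.seed(spec@seed)
    jitter <- array(stats::rnorm(nT * n * 3, sd = rep(sd, each = nT)),
                    dim = c(nT, n, 3))
    atoms <- data.frame(chain = chain, resi = as.character(seq_len(n)),
                        resn = "GLY", atom = "CA", element = "C",
                        stringsAsFactors = FALSE)
    return(structureEnsemble(atoms, jitter + rep(1, nT) %o% base))
  }
  makeReferenceEnsemble(spec, allAtom = allAtom, chain = chain)
}

#' Simulate an affinity panel from a log-linear ground truth
#'
#' `log10(affinity) = slope * wrmsd + intercept + N(0, noiseSd^2)`.
#'
#' @param wrmsds numeric scores; names become candidate ids (default
#'   `C1, C2, ...`).
#' @param slope,intercept ground-truth parameters (base-10 log scale).
#' @param noiseSd Gaussian sd on the log10 scale (>= 0).
#' @param seed integer seed.
#' @param measure,units metadata columns for the panel.
#' @return affinity panel data.frame (see [readAffinityPanel()]).
#' @export
simulateAffinityPanel <- function(wrmsds, slope, intercept, noiseSd = 0,
                                  seed = 1L, measure = "EC50",
                                  units = "nM") {
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  ids <- names(wrmsds)
  if (is.null(ids)) ids <- sprintf("C%d", seq_along(wrmsds))
  set.seed(seed)
  logv <- slope * wrmsds + intercept + stats::rnorm(length(wrmsds),
                                                    sd = noiseSd)
  data.frame(candidate_id = ids, wrmsd = unname(wrmsds),
             measure = measure, value = unname(10^logv), units = units,
             censored = FALSE, stringsAsFactors = FALSE)
}
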