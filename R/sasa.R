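#' Default van der Waals radius table
#'
#' Radii in Angstrom for the elements handled by [shrakeRupley()].
#' Elements without an entry are rejected rather than silently defaulted.
#'
#' @return named numeric vector.
#' @export
defaultAtomRadii <- function()
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# Quasi-uniform unit-sphere points on a golden-spiral (Fibonacci) lattice.
# Deterministic: no RNG involved.
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Places `nPoints` quasi-uniform test points on each atom's expanded
#' sphere (van der Waals radius + probe radius) and counts the fraction
#' not buried inside any neighbouring expanded sphere; the accessible
#' fraction times the expanded-sphere area `4 * pi * (r + probe)^2` is the
#' atom's SASA. Test points are a deterministic Fibonacci (golden-spiral)
#' lattice. A point lying exactly on k expanded spheres (including its
#' own) is shared equally between them (weight 1/k), so two coincident
#' identical atoms split one isolated sphere's area in half.
#'
#' @param xyz numeric `n x 3` matrix of atom centres (Angstrom).
#' @param elements character vector of element symbols, length `n`.
#' @param probeRadius solvent probe radius in Angstrom (water: 1.4).
#' @param nPoints number of test points per atom (>= 32).
#' @param radii named radius table; see [defaultAtomRadii()].
#' @return numeric vector of per-atom SASA in Angstrom^2.
#' @examples
#' shrakeRupley(matrix(0, 1, 3), "C")  # 4*pi*(1.7+1.4)^2 = 120.76 A^2
#' @export
shrakeRupley <- function(xyz, elements, probeRadius = 1.4, nPoints = 960,
                         radii = defaultAtomRadii()) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  n <- nrow(xyz)
  if (length(elements) != n)
    stop("elements must match the number of atoms", call. = FALSE)
  if (nPoints < 32) stop("nPoints must be >= 32", call. = FALSE)
  unknown <- setdiff(unique(elements), names(radii))
  if (length(unknown))
    stop("no radius entry for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  r <- unname(radii[elements]) + probeRadius
  unit <- fibonacciSphere(nPoints)
  tol <- 1e-9
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- unit * r[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    dc <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nbr <- which(dc < r[i] + r + tol)
    nbr <- nbr[nbr != i]
    if (!length(nbr)) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    w <- rep(1, nPoints)          # ownership weight per test point
    ties <- rep(0L, nPoints)
    for (j in nbr) {
      dj <- sqrt(rowSums(sweep(pts, 2, xyz[j, ], "-")^2))
      w[dj < r[j] - tol] <- 0
      ties <- ties + (abs(dj - r[j]) <= tol)
    }
    area[i] <- sum(w / (1 + ties)) / nPoints * 4 * pi * r[i]^2
  }
  area
}

#' Mean per-residue SASA profile of the CDR selection
#'
#' For every snapshot, computes per-atom SASA of the full structure
#' ([shrakeRupley()]), sums member atoms per selected residue, and
#' averages over snapshots to obtain `S_i`; `S_avg` is the arithmetic
#' mean of `S_i` over the selected residues. The ensemble must carry
#' all-atom records: a Calpha-only ensemble is rejected with an
#' instruction to use uniform accessibility weights instead.
#'
#' @param ensemble an all-atom [StructureEnsemble-class].
#' @param selection the [CdrSelection-class] of CDR residues.
#' @param probeRadius,nPoints,radii passed to [shrakeRupley()].
#' @return a [SasaProfile-class].
#' @export
residueSasaProfile <- function(ensemble, selection, probeRadius = 1.4,
                               nPoints = 960, radii = defaultAtomRadii()) {
  at <- ensemble@atoms
  key <- paste(at$chain, at$resi)
  if (all(tapply(rep(1L, nrow(at)), key, sum) == 1L))
    stop("Calpha-only ensemble: SASA needs all-atom records; ",
         "use uniform accessibility weights instead", call. = FALSE)
  sel <- selection@residues
  selKey <- paste(sel$chain, sel$resi)
  members <- lapply(selKey, function(k) which(key == k))
  empty <- lengths(members) == 0L
  if (any(empty))
    stop("selected residue ", selKey[which(empty)[1]],
         " has no atoms in the ensemble", call. = FALSE)
  nT <- dim(ensemble@coords)[1]
  perSnap <- matrix(NA_real_, nT, length(selKey))
  for (t in seq_len(nT)) {
    atomArea <- shrakeRupley(ensemble@coords[t, , ], at$element,
                             probeRadius = probeRadius, nPoints = nPoints,
                             radii = radii)
    perSnap[t, ] <- vapply(members, function(ix) sum(atomArea[ix]),
                           numeric(1))
  }
  sI <- colMeans(perSnap)
  names(sI) <- selKey
  new("SasaProfile", sI = sI, sAvg = mean(sI))
}

#' Write / read a per-residue SASA profile as TSV
#'
#' Columns `chain`, `resi`, `s_i`; a footer row with `chain = "AVG"`
#' carries `s_avg`.
#'
#' @param profile a [SasaProfile-class].
#' @param path TSV file.
#' @param header optional `# `-prefixed comment lines.
#' @return `readSasaTsv()`: a [SasaProfile-class].
#' @export
writeSasaTsv <- function(profile, path, header = NULL) {
  parts <- strsplit(names(profile@sI), " ")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(sprintf("# %s", header), con)
  writeLines("chain\tresi\ts_i", con)
  writeLines(sprintf("%s\t%s\t%.6f",
                     vapply(parts, `[`, character(1), 1L),
                     vapply(parts, `[`, character(1), 2L),
                     profile@sI), con)
  writeLines(sprintf("AVG\t-\t%.6f", profile@sAvg), con)
  invisible(path)
}

#' @rdname writeSasaTsv
#' @export
readSasaTsv <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  body <- tb[tb$chain != "AVG", , drop = FALSE]
  sI <- body$s_i
  names(sI) <- paste(body$chain, body$resi)
  new("SasaProfile", sI = sI, sAvg = mean(sI))
}
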