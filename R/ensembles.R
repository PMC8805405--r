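#' Construct a StructureEnsemble
#'
#' @param atoms data.frame with columns `chain`, `resi`, `resn`, `atom`,
#'   `element` (one row per atom; roster shared by all snapshots).
#' @param coords numeric array `snapshots x atoms x 3` (Angstrom).
#' @return a [StructureEnsemble-class].
#' @export
structureEnsemble <- function(atoms, coords) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resi <- as.character(atoms$resi)
  if (is.null(atoms$element)) atoms$element <- deriveElement(atoms$atom)
  if (length(dim(coords)) == 2L)
    coords <- array(coords, dim = c(1L, dim(coords)))
  new("StructureEnsemble", atoms = atoms, coords = coords)
}

# Element from an atom name: first alphabetic character of the stripped
# name (protein atoms; two-letter elements are out of scope).
deriveElement <- function(atomName) {
  nm <- gsub("[^A-Za-z]", "", trimws(atomName))
  toupper(substr(nm, 1L, 1L))
}

rosterKey <- function(df)
  paste(df$chain, df$resi, df$resn, trimws(df$atom), sep = "|")

parsePdbModel <- function(lines) {
  rec <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(rec)) return(NULL)
  num <- function(a, b) as.numeric(substr(rec, a, b))
  el <- trimws(substr(rec, 77, 78))
  atom <- trimws(substr(rec, 13, 16))
  el[el == ""] <- deriveElement(atom[el == ""])
  list(atoms = data.frame(
         chain = trimws(substr(rec, 22, 22)),
         resi = paste0(trimws(substr(rec, 23, 26)),
                       trimws(substr(rec, 27, 27))),
         resn = trimws(substr(rec, 18, 20)),
         atom = atom, element = el, stringsAsFactors = FALSE),
       xyz = cbind(num(31, 38), num(39, 46), num(47, 54)))
}

#' Read a structure ensemble
#'
#' Supported dialects: multi-model PDB (`MODEL`/`ENDMDL` with fixed-column
#' `ATOM` records; a file without `MODEL` records is a one-snapshot
#' ensemble) and a plain coordinate table (TSV with header columns
#' `model, chain, resi, resn, atom, x, y, z`). Models are ordered as in
#' the file, and the residue/atom roster is validated to be identical
#' across models; the first divergent residue is named on mismatch.
#'
#' @param path input file.
#' @param format `"auto"` (by extension: `.pdb` vs anything else),
#'   `"pdb"` or `"xyz"`.
#' @return a [StructureEnsemble-class].
#' @export
readEnsemble <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (format == "pdb") readEnsemblePdb(path) else readEnsembleXyz(path)
}

checkRoster <- function(ref, other, modelLabel) {
  kr <- rosterKey(ref)
  ko <- rosterKey(other)
  if (identical(kr, ko)) return(invisible(TRUE))
  n <- min(length(kr), length(ko))
  div <- which(kr[seq_len(n)] != ko[seq_len(n)])
  where <- if (length(div)) gsub("\\|", " ", kr[div[1]])
           else gsub("\\|", " ", kr[min(n + 1L, length(kr))])
  stop("atom roster mismatch in model ", modelLabel,
       ": first divergent residue/atom is ", where, call. = FALSE)
}

readEnsemblePdb <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {
    m <- parsePdbModel(lines)
    if (is.null(m)) stop("no ATOM records in ", path, call. = FALSE)
    return(structureEnsemble(m$atoms,
                             array(m$xyz, dim = c(1L, nrow(m$xyz), 3L))))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  models <- lapply(seq_along(starts), function(k)
    parsePdbModel(lines[starts[k]:ends[k]]))
  keep <- !vapply(models, is.null, logical(1))
  models <- models[keep]
  if (!length(models)) stop("zero models with ATOM records in ", path,
                            call. = FALSE)
  ref <- models[[1]]$atoms
  for (k in seq_along(models)[-1])
    checkRoster(ref, models[[k]]$atoms, k)
  coords <- array(NA_real_, dim = c(length(models), nrow(ref), 3L))
  for (k in seq_along(models)) coords[k, , ] <- models[[k]]$xyz
  structureEnsemble(ref, coords)
}

readEnsembleXyz <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("model", "chain", "resi", "resn", "atom", "x", "y", "z")
  if (!all(need %in% names(tb)))
    stop("coordinate table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(tb)) stop("zero models in ", path, call. = FALSE)
  ids <- unique(tb$model)                     # file order
  chunks <- lapply(ids, function(m) tb[tb$model == m, , drop = FALSE])
  mk <- function(ch) data.frame(chain = as.character(ch$chain),
                                resi = as.character(ch$resi),
                                resn = as.character(ch$resn),
                                atom = trimws(as.character(ch$atom)),
                                element = deriveElement(ch$atom),
                                stringsAsFactors = FALSE)
  ref <- mk(chunks[[1]])
  for (k in seq_along(chunks)[-1]) checkRoster(ref, mk(chunks[[k]]), ids[k])
  coords <- array(NA_real_, dim = c(length(chunks), nrow(ref), 3L))
  for (k in seq_along(chunks))
    coords[k, , ] <- as.matrix(chunks[[k]][, c("x", "y", "z")])
  structureEnsemble(ref, coords)
}

#' Write an ensemble as multi-model PDB or a coordinate table
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param path output file.
#' @param format `"pdb"` or `"xyz"`.
#' @param header optional character vector written as `REMARK` lines
#'   (pdb) or `# ` comment lines (xyz).
#' @return invisibly, `path`.
#' @export
writeEnsemble <- function(ensemble, path, format = c("pdb", "xyz"),
                          header = NULL) {
  format <- match.arg(format)
  at <- ensemble@atoms
  xyz <- ensemble@coords
  nT <- dim(xyz)[1]
  if (format == "pdb") {
    resSeq <- as.integer(sub("([0-9]+).*", "\\1", at$resi))
    icode <- sub("^[0-9]+", "", at$resi)
    name4 <- ifelse(nchar(at$atom) < 4L, sprintf(" %-3s", at$atom),
                    at$atom)
    out <- character()
    if (!is.null(header)) out <- sprintf("REMARK   1 %s", header)
    for (t in seq_len(nT)) {
      out <- c(out, sprintf("MODEL     %4d", t),
               sprintf(
                 "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 seq_len(nrow(at)), name4, substr(at$resn, 1, 3), at$chain,
                 resSeq, ifelse(icode == "", " ", icode),
                 xyz[t, , 1], xyz[t, , 2], xyz[t, , 3], 1, 0, at$element),
               "ENDMDL")
    }
    writeLines(c(out, "END"), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(sprintf("# %s", header), con)
    writeLines("model\tchain\tresi\tresn\tatom\tx\ty\tz", con)
    for (t in seq_len(nT))
      writeLines(sprintf("%d\t%s\t%s\t%s\t%s\t%.3f\t%.3f\t%.3f",
                         t, at$chain, at$resi, at$resn, at$atom,
                         xyz[t, , 1], xyz[t, , 2], xyz[t, , 3]), con)
  }
  invisible(path)
}

#' Construct a CdrSelection
#'
#' @param chain character vector of chain ids.
#' @param resi residue identifiers (coerced to character), same length.
#' @return a [CdrSelection-class] in the given order.
#' @export
cdrSelection <- function(chain, resi) {
  new("CdrSelection",
      residues = data.frame(chain = as.character(chain),
                            resi = as.character(resi),
                            stringsAsFactors = FALSE))
}

#' Build a CdrSelection from CDR maps and an ensemble roster
#'
#' Maps 0-based sequence CDR spans to the corresponding residues of each
#' chain in roster order; the light chain's residues come first, then the
#' heavy chain's, per the metric's residue ordering convention.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param lightMap,heavyMap [CdrMap-class] objects (either may be `NULL`).
#' @param lightChain,heavyChain chain ids in the ensemble.
#' @return a [CdrSelection-class].
#' @export
cdrSelectionFromMaps <- function(ensemble, lightMap = NULL, heavyMap = NULL,
                                 lightChain = "L", heavyChain = "H") {
  at <- ensemble@atoms
  pick <- function(map, ch) {
    res <- unique(at$resi[at$chain == ch])
    if (!length(res))
      stop("chain '", ch, "' not present in the ensemble", call. = FALSE)
    idx <- unlist(lapply(1:3, function(k)
      seq.int(map@spans[k, 1], map@spans[k, 2] - 1L))) + 1L
    if (max(idx) > length(res))
      stop("CDR spans extend past chain '", ch, "' (", length(res),
           " residues in roster)", call. = FALSE)
    data.frame(chain = ch, resi = res[idx], stringsAsFactors = FALSE)
  }
  parts <- list()
  if (!is.null(lightMap)) parts <- c(parts, list(pick(lightMap, lightChain)))
  if (!is.null(heavyMap)) parts <- c(parts, list(pick(heavyMap, heavyChain)))
  if (!length(parts)) stop("need at least one CdrMap", call. = FALSE)
  df <- do.call(rbind, parts)
  cdrSelection(df$chain, df$resi)
}

#' Extract the CDR Calpha coordinate tensor
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param selection a [CdrSelection-class]; output rows follow selection
#'   order, snapshots follow ensemble order.
#' @return numeric array `snapshots x N x 3`.
#' @export
extractCdrCalpha <- function(ensemble, selection) {
  at <- ensemble@atoms
  sel <- selection@residues
  caKey <- paste(at$chain, at$resi)
  idx <- vapply(seq_len(nrow(sel)), function(k) {
    hit <- which(caKey == paste(sel$chain[k], sel$resi[k]) & at$atom == "CA")
    if (!length(hit))
      stop("selected residue ", sel$chain[k], " ", sel$resi[k],
           " has no CA atom in the ensemble", call. = FALSE)
    hit[1]
  }, integer(1))
  ensemble@coords[, idx, , drop = FALSE]
}
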