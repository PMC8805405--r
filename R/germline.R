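#' Construct a GermlineTemplate
#'
#' @param geneName gene name, e.g. `"IGKV6-21*01"`.
#' @param segment `"V"` or `"J"`.
#' @param chainRole `"heavy"` or `"light"`.
#' @param residues amino-acid string.
#' @return a [GermlineTemplate-class].
#' @export
germlineTemplate <- function(geneName, segment, chainRole, residues) {
  new("GermlineTemplate", geneName = as.character(geneName),
      segment = toupper(segment), chainRole = normalizeRole(chainRole),
      residues = toupper(as.character(residues)))
}

#' Read a germline repertoire from FASTA
#'
#' Record ids are taken as gene names (first whitespace-separated token).
#' No repertoire is bundled with the package; users supply their own
#' export (e.g. from a germline gene database).
#'
#' @param path FASTA file.
#' @param segment `"V"` or `"J"`, applied to all records.
#' @param chainRole `"heavy"` or `"light"`, applied to all records.
#' @return list of [GermlineTemplate-class] objects.
#' @export
readGermlineFasta <- function(path, segment, chainRole) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(aa), function(i)
    germlineTemplate(ids[i], segment, chainRole, as.character(aa[[i]])))
  names(out) <- ids
  out
}

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

# Global (Needleman-Wunsch) alignment of two amino-acid strings.
# Returns a two-row character matrix of aligned columns (gaps as "-").
alignGlobal <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 10, gapExtension = 1)
  rbind(strsplit(as.character(Biostrings::pattern(pa)), "")[[1]],
        strsplit(as.character(Biostrings::subject(pa)), "")[[1]])
}

#' Framework sequence identity between a chain and a germline template
#'
#' Globally aligns the query chain to the template (BLOSUM62 scoring, gap
#' opening 10, extension 1) and computes identity restricted to the
#' query's framework positions: the fraction of aligned framework columns
#' (both residues non-gap) that are identical.
#'
#' @param query a [ChainSequence-class] or character string.
#' @param queryCdrs the query's [CdrMap-class], or a plain `k x 2` matrix
#'   of half-open 0-based spans.
#' @param template a [GermlineTemplate-class] or character string.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' frameworkIdentity("ACDEFG", rbind(c(2, 4)), "ACXXFG")
#' @export
frameworkIdentity <- function(query, queryCdrs, template) {
  q <- if (is(query, "ChainSequence")) query@residues else as.character(query)
  t <- if (is(template, "GermlineTemplate")) template@residues
       else as.character(template)
  if (!nchar(q) || !nchar(t))
    stop("query and template must be non-empty", call. = FALSE)
  aln <- alignGlobal(q, t)
  qpos <- cumsum(aln[1, ] != "-") - 1L      # 0-based query index per column
  inCdr <- rep(FALSE, nchar(q))
  sp <- if (is(queryCdrs, "CdrMap")) queryCdrs@spans else as.matrix(queryCdrs)
  for (k in seq_len(nrow(sp)))
    if (sp[k, 2] > sp[k, 1]) inCdr[(sp[k, 1] + 1L):sp[k, 2]] <- TRUE
  fw <- aln[1, ] != "-" & !inCdr[qpos + 1L] & aln[2, ] != "-"
  if (!any(fw))
    stop("degenerate alignment: no framework positions aligned",
         call. = FALSE)
  sum(aln[1, fw] == aln[2, fw]) / sum(fw)
}

#' Rank germline templates by framework identity
#'
#' Computes [frameworkIdentity()] of the query against every template in
#' the repertoire and ranks descending; ties are broken lexicographically
#' by gene name. The head of the ranking is the selected template.
#'
#' @param query a [ChainSequence-class].
#' @param queryCdrs the query's [CdrMap-class].
#' @param repertoire list of [GermlineTemplate-class] objects compatible
#'   with the query's chain role.
#' @return data.frame with columns `geneName`, `segment`, `identity` and a
#'   list-column `template` holding the [GermlineTemplate-class] objects,
#'   ordered by rank.
#' @export
selectTemplates <- function(query, queryCdrs, repertoire) {
  if (!length(repertoire)) stop("empty germline repertoire", call. = FALSE)
  role <- chainRole(query)
  bad <- vapply(repertoire, function(t) t@chainRole != role, logical(1))
  if (any(bad))
    stop("repertoire contains templates for the wrong chain role",
         call. = FALSE)
  ids <- vapply(repertoire, function(t)
    frameworkIdentity(query, queryCdrs, t), numeric(1))
  genes <- vapply(repertoire, function(t) t@geneName, character(1))
  ord <- order(-ids, genes)
  out <- data.frame(geneName = genes[ord],
                    segment = vapply(repertoire, function(t) t@segment,
                                     character(1))[ord],
                    identity = ids[ord], stringsAsFactors = FALSE)
  out$template <- I(repertoire[ord])
  rownames(out) <- NULL
  out
}

#' Construct a GraftDesign
#'
#' @param designId design label (e.g. `"A"` for a VL design, `"a"` for VH).
#' @param backMutations list of `c(pos, residue)` pairs or a data.frame
#'   with columns `pos` (0-based, into the grafted chain) and `residue`.
#' @return a [GraftDesign-class].
#' @export
graftDesign <- function(designId, backMutations = NULL) {
  if (is.null(backMutations) || !length(backMutations))
    bm <- data.frame(pos = integer(), residue = character(),
                     stringsAsFactors = FALSE)
  else if (is.data.frame(backMutations))
    bm <- data.frame(pos = as.integer(backMutations$pos),
                     residue = as.character(backMutations$residue),
                     stringsAsFactors = FALSE)
  else
    bm <- data.frame(
      pos = vapply(backMutations, function(x) as.integer(x[[1]]), integer(1)),
      residue = vapply(backMutations, function(x) as.character(x[[2]]),
                       character(1)),
      stringsAsFactors = FALSE)
  new("GraftDesign", designId = as.character(designId), backMutations = bm)
}

#' Read graft designs from JSON
#'
#' Format: `{"light": [{"id": "A", "back_mutations": [[pos, "R"], ...]},
#' ...], "heavy": [...]}`, or a bare list of design objects.
#'
#' @param path JSON file.
#' @return if the file has `light`/`heavy` keys, a list with those two
#'   elements (each a list of [GraftDesign-class]); otherwise a flat list.
#' @export
readDesignsJson <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  parseOne <- function(rec)
    graftDesign(rec$id, rec$back_mutations)
  if (!is.null(x$light) || !is.null(x$heavy))
    list(light = lapply(x$light, parseOne), heavy = lapply(x$heavy, parseOne))
  else
    lapply(x, parseOne)
}

# Assemble FR1 + CDR1 + FR2 + CDR2 + FR3 + CDR3 + FR4 and apply back
# mutations. `frameworks` is character(4), `cdrs` character(3).
# Returns the sequence with the product CdrMap spans as attribute "spans".
assembleGraft <- function(frameworks, cdrs, backMutations = NULL) {
  stopifnot(length(frameworks) == 4L, length(cdrs) == 3L)
  nf <- nchar(frameworks)
  nc <- nchar(cdrs)
  if (any(nc == 0L)) stop("CDR segments must be non-empty", call. = FALSE)
  starts <- c(nf[1],
              nf[1] + nc[1] + nf[2],
              nf[1] + nc[1] + nf[2] + nc[2] + nf[3])
  spans <- cbind(start = starts, end = starts + nc)
  prod <- paste0(frameworks[1], cdrs[1], frameworks[2], cdrs[2],
                 frameworks[3], cdrs[3], frameworks[4])
  if (!is.null(backMutations) && nrow(backMutations)) {
    chars <- strsplit(prod, "")[[1]]
    for (k in seq_len(nrow(backMutations))) {
      pos <- backMutations$pos[k]
      if (pos < 0L || pos >= length(chars))
        stop("back-mutation position ", pos, " out of range", call. = FALSE)
      inCdr <- any(pos >= spans[, "start"] & pos < spans[, "end"])
      if (inCdr)
        stop("back-mutation position ", pos, " lies inside a CDR",
             call. = FALSE)
      chars[pos + 1L] <- backMutations$residue[k]
    }
    prod <- paste(chars, collapse = "")
  }
  attr(prod, "spans") <- spans
  prod
}

#' Graft murine CDRs onto a germline framework
#'
#' Builds a humanized chain: frameworks FR1--FR3 from the V template,
#' murine CDR1--CDR3 substituted verbatim, FR4 from the J template (the
#' J's `W/F-G-x-G` motif starts FR4 and is included), then the design's
#' back mutations applied. The murine CDR substrings are preserved
#' exactly; back mutations inside a CDR or out of range are errors.
#'
#' @param templateV germline V [GermlineTemplate-class].
#' @param templateJ germline J [GermlineTemplate-class] (same chain role).
#' @param murine the murine [ChainSequence-class].
#' @param murineCdrs the murine chain's [CdrMap-class].
#' @param design a [GraftDesign-class]; `NULL` means no back mutations.
#' @param templateVCdrs optional [CdrMap-class] for the V template;
#'   computed with `annotateCdrs(partial = TRUE)` when missing.
#' @return list with elements `sequence` (character), `cdrs` ([CdrMap-class]
#'   of the product), `designId`, `vGene`, `jGene`, `chainRole`.
#' @export
graftChain <- function(templateV, templateJ, murine, murineCdrs,
                       design = NULL, templateVCdrs = NULL) {
  role <- chainRole(murine)
  if (templateV@segment != "V" || templateJ@segment != "J")
    stop("templateV must be a V segment and templateJ a J segment",
         call. = FALSE)
  if (templateV@chainRole != role || templateJ@chainRole != role)
    stop("template chain role does not match the murine chain",
         call. = FALSE)
  if (is.null(templateVCdrs))
    templateVCdrs <- annotateCdrs(templateV@residues, chainRole = role,
                                  partial = TRUE)
  tSeg <- segmentChain(templateV@residues, templateVCdrs)
  mSeg <- segmentChain(murine, murineCdrs)
  # FR4 starts at the J segment's W/F-G-x-G motif (motif included)
  jChars <- strsplit(templateJ@residues, "")[[1]]
  lead <- if (role == "heavy") "W" else "F"
  m0 <- findFr4Motif(jChars, lead, 0L)
  if (is.na(m0))
    stop("J template lacks the FR4 ", lead, "-G-x-G motif", call. = FALSE)
  fr4 <- substr(templateJ@residues, m0 + 1L, length(jChars))
  bm <- if (is.null(design)) NULL else design@backMutations
  prod <- assembleGraft(c(tSeg[["FR1"]], tSeg[["FR2"]], tSeg[["FR3"]], fr4),
                        c(mSeg[["CDR1"]], mSeg[["CDR2"]], mSeg[["CDR3"]]),
                        bm)
  spans <- attr(prod, "spans")
  list(sequence = as.character(prod),
       cdrs = cdrMap(spans[1, ], spans[2, ], spans[3, ], role),
       designId = if (is.null(design)) "" else design@designId,
       vGene = templateV@geneName, jGene = templateJ@geneName,
       chainRole = role)
}

#' Enumerate paired VL x VH humanized candidates
#'
#' Full cross product of grafted VL and VH chains;
#' `candidateId = "(<VL design> + <VH design>)"`.
#'
#' @param vlChains list of grafted light chains (as returned by
#'   [graftChain()]).
#' @param vhChains list of grafted heavy chains.
#' @return list of [HumanizedCandidate-class] objects of length
#'   `length(vlChains) * length(vhChains)`.
#' @export
enumerateCandidates <- function(vlChains, vhChains) {
  if (!length(vlChains) || !length(vhChains))
    stop("need at least one VL and one VH design", call. = FALSE)
  out <- list()
  for (vl in vlChains) for (vh in vhChains) {
    if (vl$chainRole != "light" || vh$chainRole != "heavy")
      stop("vlChains must be light and vhChains heavy grafts", call. = FALSE)
    id <- sprintf("(%s + %s)", vl$designId, vh$designId)
    out[[length(out) + 1L]] <- new("HumanizedCandidate",
      candidateId = id, vl = vl$sequence, vh = vh$sequence,
      vlCdrs = vl$cdrs, vhCdrs = vh$cdrs,
      provenance = list(vlDesign = vl$designId, vhDesign = vh$designId,
                        vGeneL = vl$vGene, jGeneL = vl$jGene,
                        vGeneH = vh$vGene, jGeneH = vh$jGene))
  }
  out
}

#' Write candidates as FASTA plus a TSV manifest
#'
#' @param candidates list of [HumanizedCandidate-class].
#' @param fastaPath output FASTA (two records per candidate, `_L`/`_H`).
#' @param manifestPath output TSV manifest.
#' @param header optional character vector of `# `-prefixed header lines
#'   for the manifest.
#' @return invisibly, the manifest data.frame.
#' @export
writeCandidates <- function(candidates, fastaPath, manifestPath,
                            header = NULL) {
  fa <- character()
  man <- data.frame(candidate_id = character(), vl_design = character(),
                    vh_design = character(), v_gene_l = character(),
                    j_gene_l = character(), v_gene_h = character(),
                    j_gene_h = character(), stringsAsFactors = FALSE)
  for (cand in candidates) {
    tag <- gsub("[^A-Za-z0-9]+", "", cand@candidateId)
    fa <- c(fa, sprintf(">%s_L %s", tag, cand@candidateId), cand@vl,
            sprintf(">%s_H %s", tag, cand@candidateId), cand@vh)
    p <- cand@provenance
    man <- rbind(man, data.frame(
      candidate_id = cand@candidateId, vl_design = p$vlDesign,
      vh_design = p$vhDesign, v_gene_l = p$vGeneL, j_gene_l = p$jGeneL,
      v_gene_h = p$vGeneH, j_gene_h = p$jGeneH, stringsAsFactors = FALSE))
  }
  writeLines(fa, fastaPath)
  con <- file(manifestPath, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(man, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
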