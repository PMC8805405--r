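#' Construct a ChainSequence
#'
#' @param id character label.
#' @param chainRole `"heavy"` or `"light"` (`"H"`/`"L"` accepted).
#' @param residues one-letter amino-acid string.
#' @return a [ChainSequence-class] object.
#' @examples
#' fa <- system.file("extdata", "murine_L.fasta", package = "humanizeAb")
#' ch <- readChainFasta(fa)[[1]]
#' chainRole(ch)
#' @export
chainSequence <- function(id, chainRole, residues) {
  new("ChainSequence", id = as.character(id),
      chainRole = normalizeRole(chainRole),
      residues = toupper(as.character(residues)))
}

normalizeRole <- function(role) {
  role <- tolower(as.character(role))
  if (role %in% c("h", "heavy")) return("heavy")
  if (role %in% c("l", "light", "k", "kappa", "lambda")) return("light")
  stop("chain role must be 'heavy' or 'light' (got '", role, "')",
       call. = FALSE)
}

#' Construct a CdrMap from explicit spans
#'
#' @param cdr1,cdr2,cdr3 two-integer vectors `c(start, end)`, half-open,
#'   0-based.
#' @param chainRole `"heavy"` or `"light"`.
#' @return a [CdrMap-class] object.
#' @export
cdrMap <- function(cdr1, cdr2, cdr3, chainRole) {
  sp <- rbind(CDR1 = as.integer(cdr1), CDR2 = as.integer(cdr2),
              CDR3 = as.integer(cdr3))
  colnames(sp) <- c("start", "end")
  new("CdrMap", spans = sp, chainRole = normalizeRole(chainRole))
}

igError <- function(anchor) {
  stop("not an Ig variable domain: missing ", anchor, call. = FALSE)
}

# unique occurrence of `letter` within the 0-based inclusive window [lo, hi]
findAnchor <- function(chars, letter, lo, hi, what) {
  win <- seq.int(lo, min(hi, length(chars) - 1L)) + 1L
  hits <- win[chars[win] == letter]
  if (length(hits) == 0L) igError(what)
  if (length(hits) > 1L)
    stop("ambiguous anchor: multiple ", letter,
         " residues in the expected window for ", what, call. = FALSE)
  hits - 1L  # back to 0-based
}

# first index >= from (0-based) where the FR4 motif X-G-x-G starts
findFr4Motif <- function(chars, lead, from) {
  n <- length(chars)
  i <- from
  while (i + 3L <= n - 1L) {
    if (chars[i + 1L] == lead && chars[i + 2L] == "G" && chars[i + 4L] == "G")
      return(i)
    i <- i + 1L
  }
  NA_integer_
}

#' Locate Kabat CDRs by conserved-anchor rules
#'
#' Identifies the three CDRs of an immunoglobulin variable-domain sequence
#' from its conserved anchors: the two invariant cysteines, the tryptophan
#' that opens framework 2, and the FR4 motif (`W-G-x-G` for heavy chains,
#' `F-G-x-G` for light chains). Light chains: CDR-L1 starts one residue
#' after the first Cys (expected at 0-based positions 20--26) and ends
#' before the next Trp; L2 starts 16 residues after L1's last residue and
#' is 7 residues long; L3 starts one residue after the second Cys (window
#' 85--92) and ends before the `F-G-x-G` motif. Heavy chains: CDR-H1
#' starts nine residues after the first Cys and ends before the next Trp
#' (length 5--7); H2 starts 15 residues after H1's last residue and ends
#' 33 residues before the second Cys (window 90--96; H2 length validated
#' to 16--19); H3 starts three residues after the second Cys and ends
#' before `W-G-x-G`. All spans are 0-based and half-open.
#'
#' With `partial = TRUE` the FR4 motif is not required (germline V
#' segments end within CDR3); CDR3 then extends to the end of the
#' sequence unless the motif is present.
#'
#' @param seq a [ChainSequence-class], or a plain character string (then
#'   `chainRole` is required).
#' @param chainRole chain role when `seq` is a character string.
#' @param partial logical; accept sequences lacking the FR4 anchor.
#' @return a [CdrMap-class] with the three spans.
#' @examples
#' fa <- system.file("extdata", "murine_L.fasta", package = "humanizeAb")
#' annotateCdrs(readChainFasta(fa)[[1]])
#' @export
annotateCdrs <- function(seq, chainRole = NULL, partial = FALSE) {
  if (is(seq, "ChainSequence")) {
    role <- seq@chainRole
    s <- seq@residues
  } else {
    if (is.null(chainRole))
      stop("chainRole is required for plain character input", call. = FALSE)
    role <- normalizeRole(chainRole)
    s <- as.character(seq)
  }
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (role == "light") {
    cys1 <- findAnchor(chars, "C", 20L, 26L, "first conserved Cys (light)")
    l1s <- cys1 + 1L
    wIdx <- which(chars == "W")
    wIdx <- wIdx[wIdx - 1L > l1s]  # 0-based index > l1s
    if (!length(wIdx)) igError("FR2 Trp after CDR-L1")
    l1e <- wIdx[1] - 1L            # span end = Trp position (exclusive)
    l2s <- (l1e - 1L) + 16L
    l2e <- l2s + 7L
    cys2 <- findAnchor(chars, "C", 85L, 92L, "second conserved Cys (light)")
    if (cys2 < l2e)
      stop("inconsistent anchors: second Cys precedes the end of CDR-L2",
           call. = FALSE)
    l3s <- cys2 + 1L
    fr4 <- findFr4Motif(chars, "F", l3s + 1L)
    if (is.na(fr4)) {
      if (!partial) igError("FR4 F-G-x-G motif")
      fr4 <- n
    }
    map <- cdrMap(c(l1s, l1e), c(l2s, l2e), c(l3s, fr4), "light")
  } else {
    cys1 <- findAnchor(chars, "C", 20L, 26L, "first conserved Cys (heavy)")
    h1s <- cys1 + 9L
    wIdx <- which(chars == "W")
    wIdx <- wIdx[wIdx - 1L > h1s]
    if (!length(wIdx)) igError("FR2 Trp after CDR-H1")
    h1e <- wIdx[1] - 1L
    if ((h1e - h1s) < 5L || (h1e - h1s) > 7L)
      stop(sprintf("CDR-H1 length %d outside the expected window [5, 7]",
                   h1e - h1s), call. = FALSE)
    h2s <- (h1e - 1L) + 15L
    cys2 <- findAnchor(chars, "C", 90L, 96L, "second conserved Cys (heavy)")
    h2e <- cys2 - 32L
    if (h2e <= h2s || (h2e - h2s) < 16L || (h2e - h2s) > 19L)
      stop(sprintf(
        "CDR-H2 length %d (validated against the second Cys) outside [16, 19]",
        h2e - h2s), call. = FALSE)
    h3s <- cys2 + 3L
    fr4 <- findFr4Motif(chars, "W", h3s + 1L)
    if (is.na(fr4)) {
      if (!partial) igError("FR4 W-G-x-G motif")
      fr4 <- n
    }
    map <- cdrMap(c(h1s, h1e), c(h2s, h2e), c(h3s, fr4), "heavy")
  }
  sp <- map@spans
  if (sp[3, 2] > n)
    stop("CDR3 span extends past the end of the sequence", call. = FALSE)
  if (sum(sp[, 2] - sp[, 1]) >= n)
    stop("CDR spans cover the whole sequence; not a variable domain",
         call. = FALSE)
  map
}

#' Split a sequence into framework and CDR segments
#'
#' @param seq a [ChainSequence-class] or character string.
#' @param map the chain's [CdrMap-class].
#' @return named character vector `FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4`;
#'   concatenating the pieces reproduces the input sequence.
#' @export
segmentChain <- function(seq, map) {
  s <- if (is(seq, "ChainSequence")) seq@residues else as.character(seq)
  sp <- map@spans
  n <- nchar(s)
  sub0 <- function(a, b) if (b <= a) "" else substr(s, a + 1L, b)  # 0-based
  c(FR1 = sub0(0L, sp[1, 1]), CDR1 = sub0(sp[1, 1], sp[1, 2]),
    FR2 = sub0(sp[1, 2], sp[2, 1]), CDR2 = sub0(sp[2, 1], sp[2, 2]),
    FR3 = sub0(sp[2, 2], sp[3, 1]), CDR3 = sub0(sp[3, 1], sp[3, 2]),
    FR4 = sub0(sp[3, 2], n))
}

#' Read variable-domain chains from FASTA
#'
#' One record per chain. The chain role is taken from a `_H` / `_L`
#' record-id suffix unless `chainRole` overrides it.
#'
#' @param path FASTA file.
#' @param chainRole optional role applied to all records.
#' @return list of [ChainSequence-class] objects, named by record id.
#' @export
readChainFasta <- function(path, chainRole = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(aa), function(i) {
    role <- chainRole
    if (is.null(role)) {
      if (grepl("_H$", ids[i], ignore.case = TRUE)) role <- "heavy"
      else if (grepl("_L$", ids[i], ignore.case = TRUE)) role <- "light"
      else stop("record '", ids[i],
                "' has no _H/_L suffix and no chainRole was given",
                call. = FALSE)
    }
    chainSequence(ids[i], role, as.character(aa[[i]]))
  })
  names(out) <- ids
  out
}

#' Read or write CDR spans as JSON sidecar files
#'
#' The sidecar format is authoritative when present, bypassing the anchor
#' rules: `{"chain": "H", "cdr1": [s, e], "cdr2": [s, e], "cdr3": [s, e]}`
#' with half-open 0-based intervals. A file may hold one object or a list
#' of such objects (one per chain).
#'
#' @param path JSON file.
#' @return `readCdrJson()`: a list of [CdrMap-class] objects named by
#'   chain label (`"H"`/`"L"`).
#' @export
readCdrJson <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(x$chain)) x <- list(x)
  out <- lapply(x, function(rec) {
    need <- c("chain", "cdr1", "cdr2", "cdr3")
    if (!all(need %in% names(rec)))
      stop("CDR JSON record needs fields ", paste(need, collapse = ", "),
           call. = FALSE)
    role <- normalizeRole(rec$chain)
    cdrMap(unlist(rec$cdr1), unlist(rec$cdr2), unlist(rec$cdr3), role)
  })
  names(out) <- vapply(out, function(m)
    if (m@chainRole == "heavy") "H" else "L", character(1))
  out
}

#' @rdname readCdrJson
#' @param maps a [CdrMap-class] or list of them.
#' @export
writeCdrJson <- function(maps, path) {
  if (is(maps, "CdrMap")) maps <- list(maps)
  recs <- lapply(maps, function(m) {
    sp <- m@spans
    list(chain = if (m@chainRole == "heavy") "H" else "L",
         cdr1 = sp[1, ], cdr2 = sp[2, ], cdr3 = sp[3, ])
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
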