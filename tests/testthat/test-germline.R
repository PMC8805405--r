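test_that("framework identity counts matches on framework columns only", {
  span <- rbind(c(2, 4))
  expect_equal(frameworkIdentity("ACDEFG", span, "ACXXFG"), 1.0)
  expect_equal(frameworkIdentity("ACDEFG", span, "ACXXFA"), 0.75)
  # identical frameworks, different CDRs
  ch <- toyChains()$L
  map <- annotateCdrs(ch)
  seg <- segmentChain(ch, map)
  other <- paste0(seg["FR1"], "KASQNVGTNVA", seg["FR2"], "SASYRYS",
                  seg["FR3"], "QQYSSYPYT", seg["FR4"])
  expect_equal(frameworkIdentity(ch, map, other), 1.0)
  # all-CDR span leaves no framework columns
  expect_error(frameworkIdentity("ACDEFG", rbind(c(0, 6)), "ACDEFG"),
               "no framework positions")
})

test_that("framework identity is symmetric when the CDR maps coincide", {
  ch <- residues(toyChains()$L)
  map <- annotateCdrs(ch, chainRole = "light")
  other <- ch
  substr(other, 3, 3) <- "A"
  substr(other, 60, 60) <- "T"
  substr(other, 100, 100) <- "V"
  expect_equal(frameworkIdentity(ch, map, other),
               frameworkIdentity(other, map, ch))
})

test_that("template selection ranks by identity with lexicographic ties", {
  ch <- toyChains()
  rep <- toyRepertoire()
  mapL <- annotateCdrs(ch$L)
  sel <- selectTemplates(ch$L, mapL, rep$vL)
  expect_identical(sel$geneName, c("IGKVT1*01", "IGKVT2*01"))
  expect_true(sel$identity[1] > sel$identity[2])
  expect_true(all(sel$identity[1] >= sel$identity))
  # output is a permutation of the repertoire
  expect_setequal(sel$geneName,
                  vapply(rep$vL, function(t) t@geneName, character(1)))
  # tie-break: identical sequences, different names
  twin <- list(germlineTemplate("IGKV2", "V", "light",
                                residues(rep$vL[[1]])),
               germlineTemplate("IGKV1", "V", "light",
                                residues(rep$vL[[1]])))
  tie <- selectTemplates(ch$L, mapL, twin)
  expect_identical(tie$geneName, c("IGKV1", "IGKV2"))
  expect_equal(tie$identity[1], tie$identity[2])
  expect_error(selectTemplates(ch$L, mapL, list()), "empty")
  expect_error(selectTemplates(ch$L, mapL, rep$vH), "chain role")
})

test_that("graft assembly concatenates segments and applies back mutations", {
  frs <- c("AAAA", "BBBB", "CCCC", "DDDD")
  # toy framework letters are outside the amino-acid alphabet on purpose:
  # assembly is pure string bookkeeping
  cdrs <- c("xy", "z", "qq")
  expect_identical(as.character(assembleGraft(frs, cdrs)),
                   "AAAAxyBBBBzCCCCqqDDDD")
  bm <- data.frame(pos = 1L, residue = "M")
  expect_identical(as.character(assembleGraft(frs, cdrs, bm)),
                   "AMAAxyBBBBzCCCCqqDDDD")
  expect_error(assembleGraft(frs, cdrs, data.frame(pos = 4L, residue = "M")),
               "inside a CDR")
  expect_error(assembleGraft(frs, cdrs, data.frame(pos = 21L, residue = "M")),
               "out of range")
})

test_that("identity graft returns the murine chain exactly", {
  ch <- toyChains()
  rep <- toyRepertoire()
  for (role in c("L", "H")) {
    murine <- ch[[role]]
    map <- annotateCdrs(murine)
    seg <- segmentChain(murine, map)
    tV <- germlineTemplate("SELF-V", "V", chainRole(murine),
      paste0(seg["FR1"], seg["CDR1"], seg["FR2"], seg["CDR2"], seg["FR3"],
             substr(seg["CDR3"], 1, 2)))
    tJ <- if (role == "L") rep$jL else rep$jH
    g <- graftChain(tV, tJ, murine, map)
    expect_identical(g$sequence, residues(murine))
    expect_identical(cdrSpans(g$cdrs), cdrSpans(map))
  }
})

test_that("grafted candidates conserve murine CDRs verbatim", {
  tc <- toyCandidates()
  expect_length(tc$cands, 9L)
  segL <- segmentChain(tc$murineL, tc$mapL)
  segH <- segmentChain(tc$murineH, tc$mapH)
  for (cand in tc$cands) {
    gl <- segmentChain(cand@vl, cand@vlCdrs)
    gh <- segmentChain(cand@vh, cand@vhCdrs)
    expect_identical(unname(gl[c("CDR1", "CDR2", "CDR3")]),
                     unname(segL[c("CDR1", "CDR2", "CDR3")]))
    expect_identical(unname(gh[c("CDR1", "CDR2", "CDR3")]),
                     unname(segH[c("CDR1", "CDR2", "CDR3")]))
    # length bookkeeping: template frameworks + murine CDRs
    expect_identical(nchar(cand@vl),
                     sum(nchar(gl[c("FR1", "FR2", "FR3", "FR4")])) +
                       sum(nchar(segL[c("CDR1", "CDR2", "CDR3")])))
  }
  # back mutations land where the designs say (0-based positions 6 and 40)
  byId <- setNames(tc$cands, vapply(tc$cands, function(x) x@candidateId,
                                    character(1)))
  vlA <- byId[["(A + a)"]]@vl
  vlC <- byId[["(C + a)"]]@vl
  expect_identical(substr(vlA, 7, 7), "T")   # germline residue kept
  expect_identical(substr(vlC, 7, 7), "S")   # reverted to murine
  expect_identical(substr(vlC, 41, 41), "G")
})

test_that("candidate enumeration is the labelled cross product", {
  tc <- toyCandidates()
  ids <- vapply(tc$cands, function(x) x@candidateId, character(1))
  expect_setequal(ids, as.vector(outer(c("A", "B", "C"), c("a", "b", "c"),
                                       function(x, y)
                                         sprintf("(%s + %s)", x, y))))
  vls <- list(list(sequence = tc$cands[[1]]@vl, cdrs = tc$cands[[1]]@vlCdrs,
                   designId = "A", vGene = "v", jGene = "j",
                   chainRole = "light"))
  vhs <- list(list(sequence = tc$cands[[1]]@vh, cdrs = tc$cands[[1]]@vhCdrs,
                   designId = "a", vGene = "v", jGene = "j",
                   chainRole = "heavy"))
  expect_length(enumerateCandidates(vls, vhs), 1L)
  expect_length(enumerateCandidates(rep(vls, 2), rep(vhs, 3)), 6L)
  expect_error(enumerateCandidates(list(), vhs), "at least one")
})

test_that("candidate FASTA and manifest are written coherently", {
  tc <- toyCandidates()
  fa <- withr::local_tempfile(fileext = ".fasta")
  man <- withr::local_tempfile(fileext = ".tsv")
  writeCandidates(tc$cands, fa, man)
  seqs <- Biostrings::readAAStringSet(fa)
  expect_length(seqs, 18L)
  tb <- read.delim(man)
  expect_identical(nrow(tb), 9L)
  expect_setequal(tb$vl_design, c("A", "B", "C"))
})
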