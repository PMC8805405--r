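# a small hand-built two-model PDB text, 3 residues, CA + N atoms
writeToyPdb <- function(path, dropResidueInModel2 = FALSE) {
  atomLine <- function(serial, name, resi, x, y, z)
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, "GLY", "A", resi, x, y, z, 1, 0,
            substr(name, 1, 1))
  m1 <- c("MODEL        1",
          atomLine(1, "N", 1, -1.2, 0.8, 0), atomLine(2, "CA", 1, 0, 0, 0),
          atomLine(3, "N", 2, 2.6, 0.8, 0), atomLine(4, "CA", 2, 3.8, 0, 0),
          atomLine(5, "N", 3, 6.4, 0.8, 0), atomLine(6, "CA", 3, 7.6, 0, 0),
          "ENDMDL")
  m2 <- c("MODEL        2",
          atomLine(1, "N", 1, -1.1, 0.9, 0.1), atomLine(2, "CA", 1, 0.1, 0.1, 0.1),
          atomLine(3, "N", 2, 2.7, 0.9, 0.1), atomLine(4, "CA", 2, 3.9, 0.1, 0.1),
          if (!dropResidueInModel2)
            c(atomLine(5, "N", 3, 6.5, 0.9, 0.1),
              atomLine(6, "CA", 3, 7.7, 0.1, 0.1)),
          "ENDMDL")
  writeLines(c(m1, m2, "END"), path)
  path
}

test_that("multi-model PDB parsing yields ordered snapshots with a shared roster", {
  path <- writeToyPdb(withr::local_tempfile(fileext = ".pdb"))
  ens <- readEnsemble(path)
  expect_identical(nSnapshots(ens), 2L)
  expect_identical(nResidues(ens), 3L)
  expect_equal(coords(ens)[1, 2, ], c(0, 0, 0))        # CA of residue 1
  expect_equal(coords(ens)[2, 4, ], c(3.9, 0.1, 0.1))  # CA of residue 2, model 2
  bad <- writeToyPdb(withr::local_tempfile(fileext = ".pdb"),
                     dropResidueInModel2 = TRUE)
  expect_error(readEnsemble(bad), "roster mismatch.*model 2.*A 3")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_error(readEnsemble(empty), "no ATOM records")
})

test_that("coordinate tables parse with model-order and roster validation", {
  sp <- ensembleSpec(5, 16, jitterSd = 0.3, seed = 3)
  ens <- makeReferenceEnsemble(sp)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEnsemble(ens, path, format = "xyz", header = "toy")
  back <- readEnsemble(path)
  expect_identical(nSnapshots(back), 16L)
  expect_equal(coords(back), coords(ens), tolerance = 1e-3)
  # roster mismatch: drop one row of the last model
  tb <- readLines(path)
  writeLines(tb[-length(tb)], path)
  expect_error(readEnsemble(path), "roster mismatch")
})

test_that("PDB round trip preserves coordinates to fixed-format precision", {
  sp <- ensembleSpec(7, 4, jitterSd = 0.4, seed = 9)
  ens <- makeReferenceEnsemble(sp, allAtom = TRUE)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(ens, path, format = "pdb", header = "round trip")
  back <- readEnsemble(path)
  expect_identical(nSnapshots(back), 4L)
  expect_identical(atomRoster(back)$atom, atomRoster(ens)$atom)
  expect_equal(coords(back), coords(ens), tolerance = 1e-3)
  expect_true(max(abs(coords(back) - coords(ens))) <= 5e-4 + 1e-12)
})

test_that("an independent PDB reader agrees on the written coordinates", {
  sp <- ensembleSpec(6, 3, jitterSd = 0.3, seed = 21)
  ens <- makeReferenceEnsemble(sp, allAtom = TRUE)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeEnsemble(ens, path, format = "pdb")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  expect_identical(nrow(pdb$xyz), 3L)
  ours <- coords(ens)
  for (t in 1:3) {
    theirs <- matrix(pdb$xyz[t, ], ncol = 3, byrow = TRUE)
    expect_equal(theirs, ours[t, , ], tolerance = 2e-3,
                 ignore_attr = TRUE)
  }
})

test_that("CDR Calpha extraction follows selection order and validates residues", {
  path <- writeToyPdb(withr::local_tempfile(fileext = ".pdb"))
  ens <- readEnsemble(path)
  sel <- cdrSelection(c("A", "A"), c("1", "3"))
  ca <- extractCdrCalpha(ens, sel)
  expect_identical(dim(ca), c(2L, 2L, 3L))
  expect_equal(ca[1, , 1], c(0, 7.6))
  swapped <- extractCdrCalpha(ens, cdrSelection(c("A", "A"), c("3", "1")))
  expect_equal(swapped[, 1, ], ca[, 2, ])
  expect_equal(swapped[, 2, ], ca[, 1, ])
  expect_error(extractCdrCalpha(ens, cdrSelection(c("A", "A"), c("1", "99"))),
               "99")
})

test_that("extraction is invariant to atom order within a residue", {
  sp <- ensembleSpec(4, 2, jitterSd = 0.2, seed = 5)
  ens <- makeReferenceEnsemble(sp, allAtom = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeEnsemble(ens, path, format = "xyz")
  tb <- read.delim(path)
  # reverse atom rows within each (model, residue) block
  tb2 <- do.call(rbind, lapply(split(tb, list(tb$model, tb$resi)),
                               function(ch) ch[rev(seq_len(nrow(ch))), ]))
  tb2 <- tb2[order(tb2$model), ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tb2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- cdrSelection(rep("L", 2), c("2", "4"))
  expect_equal(extractCdrCalpha(readEnsemble(path2), sel),
               extractCdrCalpha(ens, sel), tolerance = 1e-3)
})

test_that("selection built from CDR maps orders light before heavy", {
  # two-chain ensemble assembled by hand from two synthetic chains
  eL <- makeReferenceEnsemble(ensembleSpec(6, 2, jitterSd = 0, seed = 1),
                              chain = "L")
  eH <- makeReferenceEnsemble(ensembleSpec(8, 2, jitterSd = 0, seed = 2),
                              chain = "H")
  atoms <- rbind(atomRoster(eL), atomRoster(eH))
  co <- array(NA_real_, dim = c(2, nrow(atoms), 3))
  co[, 1:6, ] <- coords(eL)
  co[, 7:14, ] <- coords(eH) + 50     # keep the chains apart
  ens <- structureEnsemble(atoms, co)
  mapL <- cdrMap(c(0, 2), c(3, 4), c(5, 6), "light")
  mapH <- cdrMap(c(1, 2), c(4, 5), c(6, 8), "heavy")
  sel <- cdrSelectionFromMaps(ens, mapL, mapH)
  r <- residues(sel)
  expect_identical(r$chain, c(rep("L", 4), rep("H", 4)))
  expect_identical(r$resi[1:4], c("1", "2", "4", "6"))
  expect_identical(r$resi[5:8], c("2", "5", "7", "8"))
})
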