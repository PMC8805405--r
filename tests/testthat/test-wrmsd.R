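test_that("distance matrices are Euclidean, symmetric and isometry-invariant", {
  pts <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  D <- distanceMatrix(pts)
  expect_equal(D[1, 2], 3)
  expect_equal(D[1, 3], 4)
  expect_equal(D[2, 3], 5)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  moved <- sweep(pts %*% t(rotationMatrix(1.0, 0.3, -2.0)), 2,
                 c(5, -2, 7), "+")
  expect_lt(max(abs(distanceMatrix(moved) - D)), 1e-9)
  expect_equal(distanceMatrix(matrix(1, 3, 3)), matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_error(distanceMatrix(matrix(0, 1, 3)), "at least 2")
})

test_that("reference statistics average snapshot distance matrices", {
  # two snapshots of a residue pair at distances 4 and 6
  tens <- array(0, dim = c(2, 2, 3))
  tens[1, 2, 1] <- 4
  tens[2, 2, 1] <- 6
  ref <- referenceStats(tens)
  expect_equal(refDistances(ref)[1, 2], 5)
  expect_equal(refFluctuation(ref), c(1, 1))
  expect_equal(ref@rmsd0Avg, 1)
  # identical snapshots: zero fluctuation, d0 equals the common matrix
  same <- array(rep(triangleCoords(3, 4, 5), each = 4), dim = c(4, 3, 3))
  ref2 <- referenceStats(same)
  expect_equal(refFluctuation(ref2), rep(0, 3))
  expect_equal(refDistances(ref2), distanceMatrix(triangleCoords(3, 4, 5)),
               ignore_attr = TRUE)
  # single snapshot: valid, zero fluctuation, weights degrade with warning
  ref3 <- referenceStats(array(triangleCoords(3, 4, 5), dim = c(1, 3, 3)))
  expect_identical(nSnapshots(ref3), 1L)
  expect_warning(w <- cdrWeights(ref3), "uniform")
  expect_equal(w$wMov, rep(1, 3))
})

test_that("per-residue RMSD reproduces the hand-computed deviation example", {
  d0 <- matrix(c(0, 4, 6, 4, 0, 4, 6, 4, 0), 3, 3)
  ref <- new("ReferenceStats", d0 = d0, rmsd0I = rep(0, 3), rmsd0Avg = 0,
             nSnapshots = 1L)
  cand <- array(triangleCoords(5, 6, 4), dim = c(1, 3, 3))
  r <- rmsdPerResidue(cand, ref)
  expect_equal(r, c(sqrt(0.5), sqrt(0.5), 0), tolerance = 1e-12)
  # candidate reproducing d0 exactly scores zero everywhere
  exact <- array(triangleCoords(4, 6, 4), dim = c(1, 3, 3))
  expect_equal(rmsdPerResidue(exact, ref), rep(0, 3), tolerance = 1e-12)
  # length mismatch is an error, never realigned
  expect_error(rmsdPerResidue(array(0, dim = c(1, 4, 3)), ref),
               "one-to-one")
})

test_that("the vectorised metric matches a nested-loop oracle to 1e-10", {
  for (seed in c(2, 12, 77)) {
    set.seed(seed)
    refT <- array(rnorm(4 * 5 * 3, sd = 2), dim = c(4, 5, 3))
    candT <- array(rnorm(3 * 5 * 3, sd = 2), dim = c(3, 5, 3))
    sI <- runif(5, 5, 50)
    orc <- oracleWrmsd(refT, candT, sI = sI)
    ref <- referenceStats(refT)
    expect_lt(max(abs(refDistances(ref) - orc$d0)), 1e-10)
    expect_lt(max(abs(refFluctuation(ref) - orc$rmsd0)), 1e-10)
    expect_lt(max(abs(rmsdPerResidue(candT, ref) - orc$rmsdI)), 1e-10)
    prof <- new("SasaProfile", sI = sI, sAvg = mean(sI))
    res <- wrmsd(refT, candT, sasa = prof)
    expect_lt(abs(wrmsdValue(res) - orc$wrmsd), 1e-10)
  }
})

test_that("the score is rigid-body and snapshot-permutation invariant", {
  set.seed(4)
  refT <- array(rnorm(5 * 6 * 3, sd = 3), dim = c(5, 6, 3))
  candT <- array(rnorm(4 * 6 * 3, sd = 3), dim = c(4, 6, 3))
  base <- wrmsdValue(wrmsd(refT, candT))
  R <- rotationMatrix(0.7, 1.9, -0.4)
  expect_lt(abs(wrmsdValue(wrmsd(rigidTransformTensor(refT, R, c(9, -4, 2)),
                                 rigidTransformTensor(candT, R, c(-3, 8, 1)))) -
                base), 1e-9)
  expect_lt(abs(wrmsdValue(wrmsd(refT[c(3, 1, 5, 2, 4), , ],
                                 candT[c(4, 2, 1, 3), , ])) - base), 1e-9)
})

test_that("self-comparison equals the weighted fluctuation and vanishes iff static", {
  set.seed(6)
  refT <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  ref <- referenceStats(refT)
  res <- wrmsd(ref, refT)
  w <- cdrWeights(ref)
  expect_equal(wrmsdValue(res),
               sum(w$wAcc * w$wMov * refFluctuation(ref)) / 4,
               tolerance = 1e-9)
  expect_gt(wrmsdValue(res), 0)
  static <- array(rep(triangleCoords(3, 4, 5), each = 2), dim = c(2, 3, 3))
  expect_warning(resS <- wrmsd(static, static), "uniform")
  expect_equal(wrmsdValue(resS), 0)
})

test_that("weights follow the inverse-fraction definitions with floors", {
  ref <- new("ReferenceStats", d0 = matrix(0, 3, 3),
             rmsd0I = c(0.5, 0.5, 0.5), rmsd0Avg = 0.5, nSnapshots = 2L)
  prof <- new("SasaProfile", sI = c(10, 20, 30), sAvg = 20)
  w <- cdrWeights(ref, prof)
  expect_equal(w$wAcc, c(2, 1, 2 / 3))
  expect_equal(w$wMov, rep(1, 3))
  # doubling a residue's fluctuation halves its movability weight
  r1 <- new("ReferenceStats", d0 = matrix(0, 3, 3),
            rmsd0I = c(1, 2, 2), rmsd0Avg = 5 / 3, nSnapshots = 2L)
  r2 <- new("ReferenceStats", d0 = matrix(0, 3, 3),
            rmsd0I = c(2, 2, 2), rmsd0Avg = 2, nSnapshots = 2L)
  w1 <- cdrWeights(r1)
  expect_equal(w1$wMov[1] / w1$wMov[2], 2)
  expect_equal(cdrWeights(r2)$wMov, rep(1, 3))
  # floors with warnings
  expect_warning(wf <- cdrWeights(ref, new("SasaProfile",
                                           sI = c(0, 20, 30),
                                           sAvg = mean(c(0, 20, 30)))),
                 "floored")
  expect_equal(wf$wAcc[1], mean(c(0, 20, 30)) / 1)
  expect_warning(cdrWeights(new("ReferenceStats", d0 = matrix(0, 2, 2),
                                rmsd0I = c(1e-9, 1), rmsd0Avg = 0.5 + 5e-10,
                                nSnapshots = 2L)), "floored")
})

test_that("the scalar score is the weighted mean and is linear", {
  expect_equal(wrmsdScore(c(sqrt(0.5), sqrt(0.5), 0), rep(1, 3), rep(1, 3)),
               0.4714, tolerance = 1e-4)
  expect_equal(wrmsdScore(rep(0, 4), runif(4, 1, 2), runif(4, 1, 2)), 0)
  x <- c(0.2, 0.9, 1.4)
  wa <- c(1.2, 0.8, 1.1)
  wm <- c(0.9, 1.3, 0.7)
  expect_equal(wrmsdScore(2 * x, wa, wm), 2 * wrmsdScore(x, wa, wm))
  expect_error(wrmsdScore(x, wa[1:2], wm), "equal length")
})

test_that("batch scoring returns a ranked table over candidate ensembles", {
  sp <- ensembleSpec(8, 6, jitterSd = 0.25, seed = 14)
  ref <- makeReferenceEnsemble(sp)
  sel <- cdrSelection(rep("L", 4), as.character(c(2, 4, 6, 8)))
  cands <- list(
    near = makeCandidateEnsemble(sp, cbind(4, 0.3, 0, 0), seed = 20),
    far = makeCandidateEnsemble(sp, cbind(4, 3, 0, 0), seed = 21))
  tb <- scoreCandidates(ref, cands, selection = sel)
  expect_identical(tb$candidate_id, c("near", "far"))
  expect_identical(tb$similarity_ranking, c(1L, 2L))
  expect_true(all(diff(tb$wrmsd) >= 0))
})
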