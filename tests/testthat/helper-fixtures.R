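# Shared fixtures and independent oracles for the test suite.

ext <- function(f) system.file("extdata", f, package = "humanizeAb")

toyChains <- function() {
  list(L = readChainFasta(ext("murine_L.fasta"))[[1]],
       H = readChainFasta(ext("murine_H.fasta"))[[1]])
}

toyRepertoire <- function() {
  list(vL = readGermlineFasta(ext("germline_v_light.fasta"), "V", "light"),
       vH = readGermlineFasta(ext("germline_v_heavy.fasta"), "V", "heavy"),
       jL = readGermlineFasta(ext("germline_j_light.fasta"), "J",
                              "light")[[1]],
       jH = readGermlineFasta(ext("germline_j_heavy.fasta"), "J",
                              "heavy")[[1]],
       designs = readDesignsJson(ext("designs.json")))
}

# all nine grafted toy candidates
toyCandidates <- function() {
  ch <- toyChains()
  rep <- toyRepertoire()
  mapL <- annotateCdrs(ch$L)
  mapH <- annotateCdrs(ch$H)
  selL <- selectTemplates(ch$L, mapL, rep$vL)
  selH <- selectTemplates(ch$H, mapH, rep$vH)
  vls <- lapply(rep$designs$light, function(d)
    graftChain(selL$template[[1]], rep$jL, ch$L, mapL, design = d))
  vhs <- lapply(rep$designs$heavy, function(d)
    graftChain(selH$template[[1]], rep$jH, ch$H, mapH, design = d))
  list(cands = enumerateCandidates(vls, vhs), murineL = ch$L,
       murineH = ch$H, mapL = mapL, mapH = mapH)
}

# 3D rotation matrix from Euler-like angles
rotationMatrix <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

rigidTransformTensor <- function(tensor, R, shift) {
  out <- tensor
  for (t in seq_len(dim(tensor)[1]))
    out[t, , ] <- sweep(tensor[t, , , drop = TRUE] %*% t(R), 2, shift, "+")
  out
}

# Independent nested-loop implementation of the whole distance-matrix
# metric (reference statistics, per-residue RMSD, weights, score).
# Deliberately written with explicit quadruple loops.
oracleWrmsd <- function(refT, candT, sI = NULL) {
  euc <- function(a, b) sqrt(sum((a - b)^2))
  Tr <- dim(refT)[1]; N <- dim(refT)[2]; Tc <- dim(candT)[1]
  d0 <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    s <- 0
    for (t in seq_len(Tr)) s <- s + euc(refT[t, i, ], refT[t, j, ])
    d0[i, j] <- s / Tr
  }
  devMean <- function(tensor, Tn) {
    out <- numeric(N)
    for (i in seq_len(N)) {
      tot <- 0
      for (t in seq_len(Tn)) {
        s <- 0
        for (j in seq_len(N)) if (j != i)
          s <- s + (euc(tensor[t, i, ], tensor[t, j, ]) - d0[i, j])^2
        tot <- tot + sqrt(s / (N - 1))
      }
      out[i] <- tot / Tn
    }
    out
  }
  rmsd0 <- devMean(refT, Tr)
  rmsdI <- devMean(candT, Tc)
  wMov <- if (all(rmsd0 == 0)) rep(1, N) else mean(rmsd0) / pmax(rmsd0, 1e-6)
  wAcc <- if (is.null(sI)) rep(1, N) else mean(sI) / pmax(sI, 1)
  list(d0 = d0, rmsd0 = rmsd0, rmsdI = rmsdI,
       wrmsd = sum(wAcc * wMov * rmsdI) / N)
}

# Independent Monte-Carlo Shrake-Rupley oracle: random sphere points
# instead of a deterministic lattice, plain strict-inside burial test.
oracleSasa <- function(xyz, elements, probe = 1.4, n = 8000, seed = 1) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
  xyz <- matrix(xyz, ncol = 3)
  r <- unname(radii[elements]) + probe
  set.seed(seed)
  vapply(seq_len(nrow(xyz)), function(i) {
    v <- matrix(stats::rnorm(n * 3), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    p <- sweep(v * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n)
    for (j in seq_len(nrow(xyz))[-i]) {
      dj <- sqrt(rowSums(sweep(p, 2, xyz[j, ], "-")^2))
      acc <- acc & dj >= r[j]
    }
    mean(acc) * 4 * pi * r[i]^2
  }, numeric(1))
}

# coordinates realizing a prescribed 3-residue distance set (planar)
triangleCoords <- function(d12, d13, d23) {
  x <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y <- sqrt(d13^2 - x^2)
  rbind(c(0, 0, 0), c(d12, 0, 0), c(x, y, 0))
}
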