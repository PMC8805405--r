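---
title: "Methods: germline CDR grafting and weighted interatomic RMSD scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline CDR grafting and weighted interatomic RMSD scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humanizeAb)
```

# The problem

Humanizing a murine monoclonal antibody — grafting its six
complementarity-determining regions (CDRs) onto human germline framework
regions — routinely costs binding affinity, because the human frameworks
perturb the conformational ensemble of the grafted loops. When no
antibody–antigen co-crystal structure exists, a practical in silico
screen is to ask: *how faithfully does each humanized candidate's CDR
ensemble reproduce the murine parent's?* Candidates whose CDR geometry
and dynamics stay closest to the parent are expected to retain binding,
and the structural-similarity score turns out to track measured
affinities (EC50, K~D~) linearly on a log scale.

This package implements that screen end to end: CDR annotation, germline
template selection, V(D)J-style grafting with back mutations, candidate
enumeration, ensemble scoring, ranking, and affinity correlation.

# The score

For the `N` CDR residues (light chain first, then heavy), every snapshot
of an ensemble yields an `N x N` Cα–Cα distance matrix. With
`d^0` the murine reference's time-averaged matrix, the per-residue
interatomic RMSD of a candidate snapshot is

$$\mathrm{RMSD}_i(t) = \sqrt{\frac{\sum_{j \ne i}\bigl(d_{ij}(t) - d^0_{ij}\bigr)^2}{n}},
\qquad n = N - 1,$$

and the scalar score is the weighted mean over residues of the
snapshot-averaged RMSD:

$$\mathrm{wRMSD} = \sum_i \frac{w_{i\text{-acc}}\, w_{i\text{-mov}}\, \mathrm{RMSD}_i}{N},
\qquad
w_{i\text{-acc}} = \frac{S_{avg}}{S_i},\qquad
w_{i\text{-mov}} = \frac{\mathrm{RMSD}^0_{avg}}{\mathrm{RMSD}^0_i}.$$

`S_i` is the residue's mean solvent-accessible surface area over the
reference snapshots (solvent-exposed residues are the plausible antigen
binders and are up-weighted); `RMSD^0_i` is the reference ensemble's own
per-residue fluctuation about `d^0`, computed with the same formula
(intrinsically mobile residues carry less information about a grafted
design and are down-weighted). Both denominators are fractions of their
arithmetic means over the `N` residues, so uniform inputs give unit
weights and the score keeps units of Ångström. Because the score is
built entirely from internal distances, it never superposes structures
and is exactly invariant under rigid motion of either ensemble.

## How snapshots enter

The formula above fixes one snapshot; how a whole candidate trajectory
enters is a genuine design choice. The default treats candidate
snapshots symmetrically: `RMSD_i` is the *mean over snapshots* of
`RMSD_i(t)` against the fixed `d^0`. An alternative pooled reading,
`sqrt(mean_t RMSD_i(t)^2)`, is available via
`rmsdPerResidue(..., method = "pooled")`. Both coincide for a single
snapshot; the snapshot-mean default was chosen because it weighs every
snapshot equally on the Ångström scale rather than quadratically. All
provided snapshots are used with equal weight; no snapshot cadence or
replica structure is assumed.

## Whose ensemble supplies the weights

Both weight vectors are computed from the **murine reference** ensemble
only, so every candidate is ranked under identical weights — weights
that varied with the candidate being scored would not give a fair
comparison. `residueSasaProfile()` can of course be pointed at any
ensemble for sensitivity analysis.

## Degenerate inputs

* Reference with a single snapshot (or a static ensemble):
  `RMSD^0_i = 0` everywhere, so movability weights are undefined;
  `cdrWeights()` substitutes uniform weights with a warning.
* A single rigid residue (`RMSD^0_i < 1e-6` Å) is floored at `1e-6` Å; a
  fully buried residue (`S_i < 1` Å²) is floored at 1 Å². Both floors
  warn: they prevent one residue's weight from diverging.
* A candidate whose CDR residue count differs from the reference is a
  hard error — the metric needs a one-to-one residue map, which CDR
  grafting guarantees by construction; there is no alignment fallback.

# CDR annotation

Kabat CDRs are located by the classic conserved-anchor rules rather than
full insertion-aware renumbering: deterministic, dependency-free, and
sufficient for grafting and for extracting the CDR residue index set.
Light chains: L1 starts one residue after the first conserved Cys
(expected at 0-based positions 20–26) and ends before the next Trp; L2
starts 16 residues after L1's last residue, length 7; L3 starts one
residue after the second Cys (window 85–92) and ends before the
`F-G-x-G` FR4 motif. Heavy chains: H1 starts nine residues after the
first Cys, ends before the next Trp, length 5–7; H2 starts 15 residues
after H1's last residue and ends 33 residues before the second Cys
(window 90–96), with the implied H2 length validated against 16–19; H3
starts three residues after the second Cys and ends before `W-G-x-G`.
Note the light/heavy asymmetry at CDR3 — the third CDR begins Cys+1 on
light chains but Cys+3 on heavy chains, matching the Kabat positions of
the anchors (light: Cys 88 / L3 89; heavy: Cys 92 / H3 95).

Anchor-rule boundaries can differ by ±1 residue from a curated Kabat
assignment for unusual sequences, so explicit spans in a JSON sidecar
(`readCdrJson()`) are authoritative when present. All spans are 0-based
and half-open, which makes the FR1+CDR1+…+FR4 concatenation arithmetic
exact (`segmentChain()` round-trips any accepted sequence).

# Germline selection and grafting

Template ranking uses global (Needleman–Wunsch) alignment with BLOSUM62
scoring, gap opening 10 and extension 1, and counts identity only over
aligned framework columns of the query — the CDRs are going to be
replaced anyway, so their similarity is irrelevant to template choice.
Whether similarity should be computed over frameworks only or the whole
V region is ambiguous in practice; frameworks-only was chosen as the
reading that matches the quantity the graft actually reuses. Ties are
broken lexicographically by gene name for determinism.

The graft is pure string surgery: FR1–FR3 from the V template, murine
CDR1–3 verbatim, FR4 from the J template (the J's `W/F-G-x-G` motif
*begins* FR4 and is included). D segments need no handling because
CDR-H3 is grafted wholesale from the murine chain. Back mutations are
user-specified `(position, residue)` pairs (0-based into the grafted
chain) — published designs typically differ precisely in these sets, and
the package deliberately ships only generic machinery plus toy example
designs rather than inventing residue choices. Positions inside a CDR or
out of range are errors. No germline repertoire is bundled (licensing
and versioning); the toy repertoires under `inst/extdata/` are synthetic
sequences built to exercise the anchor rules.

# SASA

`shrakeRupley()` is the package's own implementation: test points on
each atom's expanded sphere (van der Waals radius + probe), burial
tested against every neighbour's expanded sphere. Defaults: probe 1.4 Å
(water), 960 points, radii C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å;
hydrogens count only if present in the input; an element without a
radius entry is an error, never silently defaulted.

Numerical choices worth knowing:

* The point set is a deterministic Fibonacci (golden-spiral) lattice —
  reproducible without any RNG. An isolated atom's area is exact to the
  lattice resolution (&lt;2% at 960 points; the 960 vs 5000 point
  difference on a 50-atom cluster is &lt;1%).
* A test point lying exactly on several expanded spheres is shared
  equally among them (weight `1/k`). This tie rule makes coincident
  identical atoms split one sphere's area evenly instead of
  double-counting or annihilating it.
* With a *fixed* lattice, translation invariance and the monotonicity
  property (adding a neighbour can only bury points, never free them)
  hold exactly, but rotation invariance holds only to lattice
  resolution (~1% at 960 points). These cannot all be exact
  simultaneously for any fixed finite point set: a geometry-adaptive
  lattice orientation would make rotations exact but break exact
  monotonicity. The fixed lattice was chosen; raise `nPoints` if
  tighter rotational stability is needed.

A Cα-only ensemble has no surface to integrate; `residueSasaProfile()`
rejects it and points the user at uniform accessibility weights.

# Affinity correlation

`fitLogAffinity()` is ordinary least squares of `log10(affinity)` on
wRMSD; R² is the squared Pearson correlation (invariant to the log
base; slope/intercept are reported base-10, the EC50/K~D~ convention).
Censored values ("> x") cannot enter OLS honestly and are excluded by
default; `includeCensored = TRUE` substitutes the bound for sensitivity
checks. Mixed units within a panel are an error — silent nM/M mixing
would corrupt a fit invisibly. Ranking (`rankByWrmsd()`) is ascending
with min-tie ranks.

The bundled panels under `inst/extdata/` carry published wRMSD and
affinity values for four humanized antibody series (anti-TNF-α,
anti-EGFR, anti-GPC3, anti-α4β1 integrin) at the printed precision.
Refitting them reproduces the published R² values to within ~0.005 —
except the anti-TNF-α K~D~ panel, where refitting the rounded printed
values gives ≈0.985 rather than the published 0.9921; the original fit
evidently used unrounded scores. The discrepancy is documented here
rather than resolved.

# The synthetic generator

`makeReferenceEnsemble()` emulates an MD-like ensemble as independent
per-residue Gaussian jitter about a fixed base conformation (helix,
extended, or seeded random walk; 3.8 Å virtual Cα bonds), and
`makeCandidateEnsemble()` adds a systematic displacement of chosen
residues — the caricature of a humanized candidate whose grafted loop
sits slightly off. `simulateAffinityPanel()` draws affinities from the
log-linear ground truth `log10(A) = slope·wRMSD + intercept + ε`,
`ε ~ N(0, σ²)`.

What this emulates — and deliberately does not: real trajectories have
correlated, anharmonic, multi-basin motions; real residues have side
chains; real affinity panels have measurement structure beyond i.i.d.
log-normal noise. Passing the synthetic recovery tests therefore shows
the *machinery* is correct (the score responds monotonically to a known
displacement, weights respond inversely to known flexibility, the
regression recovers known parameters), not that any particular real
antibody will be predicted well. All randomness is R's default
Mersenne-Twister under an explicit recorded seed; identical seeds give
bit-identical ensembles, and generated PDB fixtures survive the
round trip through `readEnsemble()` at the format's 3-decimal precision.
Dummy all-atom mode places four idealized backbone atoms per residue —
enough for SASA to integrate, with no claim of chemistry.

Problem sizes used in the shipped tests and acceptance script — 5–12
residues, 1–16 snapshots for exact/oracle checks, 400–2000 snapshots for
Monte-Carlo calibrations, 200 replicate fits for the slope-recovery
check — are the package's choice of smallest sizes at which each
property is sharply testable.

# Known limitations

* Anchor-rule CDR annotation is not insertion-aware Kabat renumbering;
  unusual chains (nanobodies, TCRs, heavily mutated frameworks) need
  sidecar spans or will be rejected.
* The score compares CDR geometry only; it knows nothing about
  framework–antigen contacts, VH–VL orientation shifts, or binding
  energetics.
* Multi-model PDB and the plain coordinate table are the only
  trajectory formats; binary MD formats (DCD/XTC/NetCDF) should be
  exported to one of these first.
* The log-linear affinity relation is an empirical observation on small
  panels; extrapolating a fit far outside the observed wRMSD range is
  not advised.

# A worked miniature

```{r example, eval = FALSE}
ext <- function(f) system.file("extdata", f, package = "humanizeAb")

# humanize the toy murine chains
ql <- readChainFasta(ext("murine_L.fasta"))[[1]]
qh <- readChainFasta(ext("murine_H.fasta"))[[1]]
mapL <- annotateCdrs(ql); mapH <- annotateCdrs(qh)
selL <- selectTemplates(ql, mapL,
  readGermlineFasta(ext("germline_v_light.fasta"), "V", "light"))
designs <- readDesignsJson(ext("designs.json"))

# score synthetic ensembles of increasing CDR displacement
sp <- ensembleSpec(12, 50, jitterSd = 0.3, seed = 1)
sel <- cdrSelection(rep("L", 12), as.character(1:12))
refT <- extractCdrCalpha(makeReferenceEnsemble(sp), sel)
sapply(c(0.5, 1, 2, 4), function(a)
  wrmsdValue(wrmsd(refT, extractCdrCalpha(
    makeCandidateEnsemble(sp, cbind(6, a, 0, 0), seed = 2), sel))))

# correlate published scores with published affinities
fitLogAffinity(readAffinityPanel(ext("anti_gpc3_ec50.tsv")))
```
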