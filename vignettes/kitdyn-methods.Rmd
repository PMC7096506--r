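---
title: "Methods: screening and conformational analysis of full-length RTK models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and conformational analysis of full-length RTK models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kitdyn)
```

## The problem

Type III receptor tyrosine kinases carry a 60–100-residue kinase insert
domain (KID) splitting the kinase domain, plus a long C-terminal tail;
both are deleted or unresolved in every crystal structure, although they
carry most of the receptor's phosphorylation sites. A full-length
cytoplasmic-domain model is therefore a hybrid object: a crystallographic
kinase domain with a de-novo-modelled insert, whose plausibility must be
argued statistically — first by screening candidate inserts against the
crystallographic evidence, then by comparing the conformational behaviour
of the surviving candidates in molecular-dynamics simulation. `kitdyn`
implements both stages as reproducible, deterministic computations.

## The screening model

A candidate model is a coordinate set plus three annotations: the
end-to-end distance *d* between the two residues flanking the KID (Cα–Cα;
for KIT, F689 and D768), an externally supplied model-quality score
(energy-like, lower better — e.g. a statistical potential from the
modelling program), and a per-residue secondary-structure string. The
screening funnel is:

1. **Distance filter.** Keep models with |*d* − *d*~ref~| ≤ tol. The
   defaults *d*~ref~ = 9.9 Å, tol = 1.0 Å are the crystallographic value
   of the autoinhibited KIT kinase domain and a conventional tolerance;
   the bounds are inclusive (the natural reading of "9.9 ± 1.0 Å" — a
   model at exactly 10.9 Å is kept).
2. **Clash screen.** Reject models with any non-bonded (non-consecutive)
   atom pair under 1.5 Å. This replaces the visual elimination of models
   with intramolecular "nodes": a reproducible, recorded criterion in
   place of eyeballing.
3. **Score ranking.** Keep the k best scores (default k = 26), ties
   broken by model id so the pipeline is a pure function of its inputs.
4. **SS-similarity clustering.** Pairwise distance between SS strings is
   1 − (fraction of identical positions) — the simplest positional
   semimetric; the score is recorded in the output so an alternative
   (e.g. segment-overlap) could be swapped without touching the tree
   code. Clustering is agglomerative under farthest-point (complete)
   linkage, `d(u,v) = max(dist(u[i], v[j]))`, whose merge heights are
   provably non-decreasing; minimum-distance ties merge the
   smallest-index pair.
5. **Representatives.** Each cluster contributes its medoid (minimum
   summed distance to members, ties by id). The default cut at 4
   clusters reflects how many distinct candidates one can realistically
   carry into extended MD. Medoid selection again replaces a visual
   choice with a deterministic one.

## Trajectory metrics

All comparative metrics operate on Cα atoms: Cα-only analysis is the
field's convention for backbone dynamics and is what the annotations of
candidate models provide. The atom pair behind *d* is likewise taken as
Cα–Cα; nothing in the workflow requires side-chain coordinates.

Superposition is the weighted Kabsch solution via SVD with the
reflection branch corrected to a proper rotation (det = +1); degenerate
(collinear) references are rejected rather than silently resolved. RMSD
series fit on one region and measure on another when asked — fitting the
whole protein and measuring a domain gives its "all displacements"
curve, fitting the domain itself its "internal components" curve, and
their per-frame difference isolates rigid displacement relative to the
rest (which can be negative on individual frames; no sign is asserted).

RMSF discards a configurable burn-in (non-equilibrated frames), fits
each retained frame on a fit region, and measures per-atom RMS deviation
from the time-average position. `RMSD100 = RMSD / (1 + ln √(N/100))`
makes RMSDs of different-sized domains comparable; the denominator
vanishes near N ≈ 13, so N ≥ 20 is enforced. The radius of gyration is
mass-weighted by default (standard atomic masses inferred from atom
names) with uniform weights for bead models.

The Ramachandran check computes φ/ψ from backbone dihedrals, excludes
glycine and proline as is customary, and scores against a coarse
favored+allowed region map (right-handed α, β/extended with its ψ
wrap-around, left-handed α) shipped as explicit rectangles via
`ramachandranRegions()`. The map is deliberately generous and published
in full rather than hidden in code; which exact "allowed" definition a
given validation program uses is never fully specified, so the map is a
declared package choice.

## Secondary structure

Assignment follows the Kabsch–Sander logic: backbone N–H···O=C hydrogen
bonds by the electrostatic model E = 0.084·332·(1/r~ON~ + 1/r~CH~ −
1/r~OH~ − 1/r~CN~) kcal/mol with the standard −0.5 kcal/mol cutoff;
amide hydrogens reconstructed 1.01 Å from N along the bisector of the
C′(i−1)→N and Cα→N directions when absent (the first residue and
prolines donate nothing). Two consecutive n-turns make a helix (n = 4
'H', 3 '3₁₀/G', 5 'π/I'); parallel/antiparallel bridge patterns make
strands, with isolated bridges 'B' and laddered ones 'E'; remaining turn
residues 'T'; Cα-curvature bends over 70° 'S'; else coil. The priority
order H > E > B > G > I > T > S matches classical precedence. Residues
with incomplete backbones are assigned 'C' and flagged rather than
dropped, so timeline matrices stay rectangular.

Conservation against a template assignment merges H/G/I before
comparison: the scientific claim being scored is helix persistence, not
subtype identity; strand subtypes stay distinct.

## Essential dynamics and correlation maps

The positional covariance is accumulated after removing rigid-body
motion: either one fit to the initial conformation, or the iterative
average fit (fit → recompute mean → refit) with a 1e-6 Å convergence
threshold on the mean, capped at 50 iterations. PCA is a symmetric
eigen-decomposition; eigenvalues below zero by numerical noise are
clamped, and each eigenvector is signed so its largest-magnitude
component is positive — a pure reporting convention making outputs
reproducible across LAPACK builds. Mode export writes mean ± 2√λ·v as a
two-frame PDB; the ±2σ scaling is a visualization convention recorded in
the output. Cross-correlation maps are the per-atom-pair block traces of
the same covariance, normalized to [−1, 1]; a zero-fluctuation atom
would make the normalization 0/0, so its off-diagonal row is zeroed and
the atom flagged.

## Conformational clustering and transitions

k-means uses Lloyd iterations on k-means++ seeds, best of 10 restarts by
inertia, fully determined by an explicit seed. The feature space is the
flattened, fitted Cα coordinates (Euclidean metric); a PCA pre-reduction
is deliberately not applied by default. Cluster number selection runs
k-means across a range and takes the Calinski–Harabasz argmax; when the
Davies–Bouldin argmin disagrees, the smaller k wins and the conflict is
recorded with both index curves — parsimony as the declared tie-break
between two indices the literature treats as co-equal. A
zero-within-dispersion clustering yields DB 0 and CH flagged infinite.

RMSD histograms use 1000 equal-width bins over [0, 1.05·max] and are
area-normalized; modes are counted on a lightly smoothed density with a
prominence floor (10% of the maximum by default). Change-point detection
is exact dynamic programming over piecewise-constant fits up to 5
changes, with the model chosen by n·log(SSE/n) + 3·m·log(n); a constant
series yields zero changes by construction (the SSE floor makes all
models equal and the penalty picks the smallest). The BIC-style factor 3
is a conventional conservative choice for correlated MD series — the
transitions this tool localizes were found by eye in the original
workflow, so the detector is plumbing with declared defaults, not a
fitted model.

## Consensus

Candidate reports carry per-domain RMSD mean/sd (each domain fitted on
itself against the initial conformation), per-domain mean RMSF, the *d*
series mean/sd and |mean − *d*~ref~|, the KID radius-of-gyration mean/sd
(the KID is the region whose compactness discriminates candidates), SS
conservation of the kinase lobes against the template, and a plateau
flag (OLS slope over the final quarter within twice its standard error —
a minimal formalization of "the curve has flattened"). Aggregation is an
unweighted rank sum: the original argument is a qualitative consensus
across independent metrics, and Borda is its minimal formalization;
weights are exposed for sensitivity analysis. Ties break on |*d* −
*d*~ref~| then id. A metric missing for any candidate (e.g. SS
conservation for Cα-only models) is dropped from the aggregation and
noted, never imputed.

## What the synthetic generators emulate — and what they do not

The generators reproduce the *statistical* structure each stage assumes:
self-avoiding Cα bead chains with ~3.8 Å virtual bonds and named domain
schemes whose reference pair flanks the KID-like middle domain;
Gaussian-fluctuation trajectories whose covariance is exactly a planted
spectrum (directions drawn orthogonal to the six rigid-body modes, so
they represent purely internal motion — what survives least-squares
fitting); two-state trajectories with a known switch window; candidate
ensembles with exactly imposed *d* values, SS group templates with flip
noise, and Gaussian scores. Secondary-structure fixtures are ideal
backbones built by natural-extension-reference-frame placement with
standard bond geometry, including a calibrated two-strand antiparallel
sheet.

They are not molecular dynamics: no force field, no thermostat, no
solvent, no anharmonicity, no coupling between *d*, Rg and SS content.
Passing recovery tests therefore demonstrates that the estimators are
correct and well-calibrated on data satisfying their own model
assumptions — not that any biological conclusion about KIT transfers.
Real trajectories add fat-tailed fluctuations, slow drift and
correlated noise that the planted-spectrum tests do not probe.

Default problem sizes — 40–60 beads, 300–5000 frames, 2000-model
ensembles, 1000-point series — were chosen as the smallest scales at
which the recovery targets (10% on spectra, ±2% on transition windows,
ARI ≥ 0.95 on planted clusters) are comfortably identifiable; they run
in seconds to tens of seconds on one core.

## Numerical choices and degenerate inputs

* Kabsch: < 3 points or collinear references error; weights must be
  non-negative with positive sum.
* Iterative average fit: 1e-6 Å mean-shift tolerance, 50-iteration cap.
* PDB coordinates are fixed-width %8.3f, so round-trips are exact to
  1e-3 Å; altlocs resolve to the highest-occupancy copy (ties to 'A');
  insertion-coded residues are kept as distinct residues; multi-chain
  files use the first chain for scheme-based analysis.
* The KIT scheme stores the published domain bounds verbatim, including
  the V936/K936 boundary tension between the template's last residue and
  the C-terminal domain's first — recorded in the scheme's notes rather
  than silently reconciled. The strict KID (Q694–T753) and the elongated
  KID (F689–D768) necessarily overlap, so the elongated range lives in a
  separate analysis-range table and the domain table proper stays
  non-overlapping.
* All tie-breaks (score ranking, medoids, linkage merges, consensus) are
  by id or smallest index, making every pipeline output byte-identical
  across repeated runs at a fixed seed.

## Limitations

* The SS assigner is a faithful but simplified Kabsch–Sander
  implementation: ladders are detected by bridge adjacency rather than
  full ladder/sheet bookkeeping, and chain breaks are handled by residue
  flagging, not by the original's break symbols.
* The clash screen is a heavy-atom distance floor; it does not detect
  knots or threaded topologies that are clash-free.
* External model-quality scores are consumed, never computed: the
  statistical potential belongs to the modelling program that produced
  the candidates.
* Binary trajectory formats are out of scope; multi-model PDB is the
  interchange dialect, keeping the package dependency-light and its
  fixtures plain text.
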