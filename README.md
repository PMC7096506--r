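# kitdyn

Model screening and conformational-dynamics analysis for the full-length
KIT cytoplasmic domain — and, more generally, for any multi-domain
receptor-tyrosine-kinase construct whose structure must be assembled from
a crystallographic kinase domain plus de-novo-modelled insert regions.

Crystal structures of type III receptor tyrosine kinases (KIT, PDGFR,
CSF1R, FLT3) systematically lack the kinase insert domain (KID) and the
C-terminal tail. Building a full-length cytoplasmic-domain model therefore
means generating thousands of candidate insert conformations, screening
them against the crystallographic evidence, and discriminating the
surviving candidates by their behaviour in molecular-dynamics simulation.
`kitdyn` implements that workflow end to end for users who already have
candidate coordinates (from fragment assembly or comparative modelling)
and trajectories (from any MD engine able to write multi-model PDB):

1. **Model screening** — candidate models are filtered on the end-to-end
   distance *d* between the residues flanking the KID (F689–D768 in KIT;
   the crystallographic value is 9.9 Å and the default window 9.9 ± 1.0 Å,
   bounds inclusive), screened for steric clashes, ranked on an external
   model-quality score (DOPE-like, lower = better), clustered by
   secondary-structure similarity under farthest-point linkage
   (`d(u,v) = max dist(u[i], v[j])`), and reduced to one medoid
   representative per cluster.
2. **Trajectory metrics** — Kabsch least-squares superposition, per-domain
   RMSD/RMSF with configurable fit and measurement regions, radius of
   gyration, the size-normalized `RMSD100 = RMSD / (1 + ln √(N/100))`,
   per-frame *d* tracking, and Ramachandran allowed-region fractions.
3. **Secondary structure** — a Kabsch–Sander-style assigner (backbone
   H-bonds by the −0.5 kcal/mol electrostatic criterion, then
   n-turn/bridge pattern rules over the 8-letter H/G/I/E/B/T/S/C
   alphabet), SS timelines, per-residue occupancy percentages and
   conservation scores against a template assignment.
4. **Essential dynamics** — positional covariance after iterative
   average-structure fitting, PCA (`C = V Λ Vᵀ`), cumulative variance,
   porcupine-style mode export, and dynamic cross-correlation maps
   (`C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)`).
5. **Conformational clustering** — k-means (k-means++ seeding, restarts)
   with Davies–Bouldin and Calinski–Harabasz model selection, RMSD
   histograms with mode counting, internal-vs-displacement RMSD
   decomposition, and dynamic-programming change-point detection.
6. **Consensus selection** — a per-metric rank-sum (Borda) aggregation of
   the candidate reports: lower RMSD/RMSF means and spreads, smaller
   |d − d_ref| and Rg spread, higher SS conservation.
7. **Synthetic data** — seeded generators for self-avoiding Cα bead
   proteins with domain schemes, Gaussian-fluctuation trajectories with
   planted PCA spectra, two-state transition trajectories, ideal
   helix/strand backbones, and candidate ensembles with known ground
   truth, so every stage is testable without external downloads.

## Worked example

Screen a synthetic 2000-model ensemble and rank four candidate
trajectories:

```r
library(kitdyn)

ens <- generateCandidateEnsemble(list(nModels = 2000), seed = 1)
out <- screenPipeline(ens$models, ens$scheme,
                      targetD = 9.9, tol = 1.0, kTop = 26, nClusters = 4)
out$report$counts
#>           input        distance           clash           score representatives
#>            2000             644             639              26               4
```

2000 generated models reduce to 644 within the 9.9 ± 1.0 Å window, 639
after the clash screen, the 26 best-scoring survivors are clustered by SS
similarity, and 4 medoid representatives remain — the screening funnel a
hybrid modelling protocol produces before MD.

Candidate discrimination on four trajectories (the third built with the
smallest planted fluctuations and *d* at the reference — the
"well-behaved" model):

```r
reports <- lapply(names(trajs), function(id)
  candidateMetrics(trajs[[id]], scheme, dRef = 9.9, burnIn = 40, id = id))
rk <- consensusRank(reports)
rk
#> ConsensusRanking: M3 > M4 > M2 > M1
rk@scores
#> M1 M2 M3 M4
#> 20 15  5 10
```

M3 wins with rank-sum 5 (first on five of six metrics); its end-to-end
distance over the production window is 9.90 Å (sd 0.20) and its KID
radius of gyration 8.86 Å (sd 0.02) — stable *d* at the crystallographic
value and a compact, low-variance KID are exactly the signatures the
consensus rewards. Essential dynamics of the winner:

```r
ed <- pcaED(covarianceED(trajs$M3, fitTarget = "average"))
ed
#> EssentialDynamics: 120 coordinates ( 40 atoms )
#>   top eigenvalue 0.3191 A^2; 10 modes cover 100.0% variance
```

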