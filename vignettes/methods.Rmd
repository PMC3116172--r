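---
title: "Binary QSAR modeling of a multi-cell-line inhibitor series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary QSAR modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bqsar)
```

## The problem

A medicinal-chemistry series — here, a 93-compound natural-product
derivative library assayed against four tumor cell lines (BxPC-3,
NCI-H446, SW1990, NCI-H157) — poses three linked questions:

1. Which descriptor family carries the structure–activity signal:
   physicochemical ("general") descriptors or topological drug-like-index
   (DLI) counts?
2. Does the training/testing division scheme (global max–min diversity
   ranking vs. per-cluster diversity ranking) change the conclusions?
3. Which statistical back-end is appropriate for noisy cytotoxicity data:
   regression (PLS, support vector regression) or binary classification
   (Bayesian histogram classifier, support vector machine)?

`bqsar` implements the complete workflow — descriptors, division, four
model back-ends, metric grids with descriptor-set difference (σ) columns,
a paired t-test across division schemes, and an R-group suggestion
engine — with a seeded synthetic-library generator so that every stage is
testable end to end.

## Descriptors

Commercial descriptor definitions are proprietary, so the package
implements documented open analogues. The downstream pipeline requires
only a deterministic, atom-order-invariant compound → vector map.

**General (physicochemical), 19 values.** Additive atomic-contribution
logP and molar refractivity over a compact atom-type table (aliphatic /
aromatic carbon split by heteroatom attachment, amine / amide / aromatic
nitrogen, hydroxyl / ether / carbonyl oxygen, halogens, hydrogens typed by
the heavy atom they ride on); molecular weight; approximate per-atom van
der Waals surface areas (sphere area minus one spherical cap per
neighbour, Bondi radii, idealized bond lengths from covalent radii),
reported in total and partitioned into bins of the per-atom logP, molar
refractivity, and partial-charge contributions; and summary statistics
(positive sum, negative sum, extrema) of PEOE partial charges computed
with six damped electronegativity-equalization sweeps (the sweep count is
fixed for determinism).

**Drug-like index (topological), 11 values.** Ring count (cyclomatic
number), ring atoms, fused ring systems, linker atoms (acyclic atoms
surviving iterative terminal pruning but outside rings), framework size
(rings plus linkers), side-chain atom counts split into carbon and
heteroatom, and a scalar index `2·rings + ring_systems + 0.5·linkers +
0.1·framework + 0.05·side_chain` that weights the structural hierarchy
from its cyclic core outward. The algebraic form of the scalar is a
package choice; only its monotone dependence on the hierarchy counts
matters downstream.

Normalization for distance computations is a z-score per column using the
population (root-mean-square) standard deviation, computed on the full
library *before* division — the max–min ranking must see all compounds on
one scale. Zero-variance columns are dropped with a warning.

Aromaticity perception is deliberately approximate (ring atoms incident
to in-ring double bonds, or explicit order-4 bonds). The synthetic series
is fully saturated, so nothing in the shipped workflow depends on exact
Hückel perception; users feeding aromatic SDF input get consistent,
Kekulé-derived flags.

## Dataset division

`rank_diverse()` is the greedy max–min rule: the first library entry
seeds the ranking; each subsequent rank goes to the compound whose
minimum Euclidean distance to the already-ranked set is largest, ties
broken toward the lower file index so results are reproducible. The
training set is the first ⌊0.65·N + 0.5⌋ entries (round-half-up, test set
kept non-empty); for N = 93 this yields the 60/33 partition whose
denominators recur in the reference results grid.

The cluster-then-diversify scheme runs the same ranking inside each
cluster with per-cluster round-half-up (singletons go to training). The
original descriptor-based clustering algorithm is undocumented, so a
seeded k-means (k = max(2, round(N/20)), 10 restarts) stands in, and the
clustering is pluggable — `cluster_diverse_split()` accepts any label
vector. A labeling with cluster sizes {23, 23, 24, 23} reproduces the
61/32 partition implied by the published per-cluster accuracies. Both
division schemes are computed once, in the z-scored space of the first
requested descriptor set, and shared across descriptor sets so that σ
columns compare models on identical partitions.

## Model back-ends

All four models consume raw (unstandardized) descriptor matrices; each
applies its own internal scaling.

**PLS.** NIPALS PLS1 after a principal-component pre-filter of the
descriptor correlation matrix: eigendirections with
λ_max/λ > condition limit (default 10^6) are discarded, so duplicated or
collinear descriptor blocks cannot destabilize the fit. The component
limit is unbounded by default; extraction stops when the residual
activity sum of squares falls below 10^-16 of the uncentered total — an
essentially constant response therefore retains zero components and
reduces to the intercept. The regression target is y = log10(IC50)
throughout: potency spans orders of magnitude, and the log scale is what
makes the noiseless-linear limit checks meaningful.

**SVR / SVM.** ε-insensitive RBF support vector regression and C-SVM
classification delegate to libsvm (package e1071) behind the package's
configuration surface. Defaults follow standard heuristics — kernel width
1/n_features, cost 1, ε = 0.1 — and are deliberately not tuned: the
workflow compares model *families*, not tuned incarnations. A constant
regression response yields a constant predictor rather than an error.

**Binary Bayes.** The centerpiece. Activities are binarized against a
per-cell-line IC50 cutoff — the positive control's own IC50 (38.11, 9.13,
61.05, 58.33 μg/mL for BxPC-3, NCI-H446, SW1990, NCI-H157); a compound
at least as potent as the control (IC50 ≤ cutoff; the boundary counts as
active) is labeled active. For each descriptor the training values are
rescaled to [0, 1] over the training range and accumulated into 25
equal-width bins per class; each histogram is convolved with a Gaussian
kernel of width σ = 0.25 in normalized-range units (a deliberately heavy
smoothing that removes bin-boundary sensitivity), floored at 10^-9 per
bin, and renormalized. Prediction multiplies the per-descriptor
likelihoods naively with the class priors and normalizes over the two
classes; a descriptor whose class histograms coincide contributes a
constant factor and drops out. Out-of-range query values clamp to the
boundary bin. The bin count is configurable; the smoothing width is the
documented constant of the method.

**Evaluation.** Regression reports R² (training self-fit), Q² and RMSE
(leave-one-out on training), r² (independent test); classification
reports At / Av / Ap (training self-fit, leave-one-out, independent
test). All squared correlations are Pearson correlations squared — never
1 − SS_res/SS_tot — because the reference grid contains r² = 0.000 cells
alongside nonzero RMSE, which only a correlation definition produces.
When predictions are constant the correlation is undefined and reported
as 0. Classification accuracies retain their integer numerators and
denominators so every printed value is reconstructable as n/D. A
leave-one-out fold whose refit degenerates (single class after removal)
predicts the majority label of the remaining rows and is logged.

## Grids, σ columns, and the division t-test

Results assemble into a long grid over (division, model, metric, cell
line, descriptor set). `sigma_columns()` computes σ = drug_like − general
at full precision; rounding to three decimals happens only at rendering,
which also stars the per-cell-line maximum independent-test accuracy.
`paired_ttest()` pairs every non-σ cell of the two division grids — the
pairing universe is recorded in its output for auditability — and runs a
two-sided paired t-test; identical grids (zero-variance differences) are
reported as degenerate rather than given a fabricated p-value.

The package ships the published results grid of the emulated study
(`reference_grid()`) as printed, including its σ entries. One cell's
printed σ disagrees in sign with its own row values (a transcription
error in the source); the test suite asserts exact 3-decimal agreement on
the 95 consistent cells and magnitude agreement on that one.

## The suggestion engine

`match_scaffolds()` assigns each compound to the first scaffold (priority
order) whose core embeds as an induced, element- and bond-order-exact
subgraph (igraph's LAD solver with element-restricted domains) such that
every non-core atom belongs to a fragment attached at exactly one declared
position. R-group identity uses canonical graph keys (BLISS canonical
permutation with element colors plus incident-bond-order sums; exact for
the single-bond fragments manipulated here).

`enumerate_chimeras()` forms, for every matched molecule, position, and
R-group observed at that position in another same-scaffold molecule, one
hypothetical single-point mutant; the pool is deduplicated by the full
(scaffold, position → R-group) map and purged of molecules already in the
input set. When several single-point routes generate the same chimera,
the suggestion table attributes it to the route with the largest
predicted activity gain over its parent — the modification actually
responsible for the improvement; the underlying method leaves this
attribution open, and all routes remain available in the enumeration
output.

Scoring: `score = P(active | chimera) − mean P(active | input library)`,
so 0 means "as likely active as an average input molecule" and the
printed percentage gain is 100·score; by construction the scores of the
input molecules themselves average to zero. The weight is the mean, over
same-scaffold inputs, of the fraction of positions bearing an identical
R-group — a [0, 1] measure of the statistical base behind the suggestion.
Ranking is score × weight, ties broken by weight then parent id.
Cross-scaffold R-group borrowing is disallowed (equivalent positions are
defined only within a scaffold), and unmatched compounds inform the
probability baseline but not the enumeration.

## The synthetic generator

`generate_library()` emulates the statistical structure of the study
series: 93 compounds, four saturated polycyclic scaffolds (three share a
ring nitrogen; matching priority S1 > S2 > S3 > S4), six acyclic decoys
that match no scaffold, four cell lines with the positive-control cutoffs
above, and an additive activity model
log10 IC50 = baseline + Σ coefficients(position, R-group) + N(0, sd).

Three modification routes are planted on the signal cell line (the
NCI-H446 analogue): demethylation at position 8 (a ring-nitrogen
methylation site, coefficient −0.75 for H vs +0.45 for methyl),
methylation at position 7 (a ring-carbon site, ∓0.10–0.15), and
hydroxylation at position 11 (∓0.15–0.25), with fluorination at position
3 as a neutral decoration. Placing the dominant signal on the nitrogen
makes position 8 physicochemically distinct from position 7, so additive
descriptors can resolve *which* position a methyl occupies — a structural
necessity, because purely additive descriptor sums are otherwise
position-blind. Effect sizes make position 8 decide the activity label
with a ≥3σ margin (noise sd 0.12), while positions 7/11 remain real but
small; their near-independence from the label exercises the Bayes
model's descriptor drop-out behaviour. The three noise cell lines have
zero coefficients, baselines at their cutoffs, and noise sd 0.45 —
non-specific cytotoxicity with near-balanced labels. The R-group
vocabulary spans roughly sixteen combinations per scaffold, comfortably
above the per-scaffold compound count, so single-point mutation
enumeration always yields a genuine pool of novel hypothetical
molecules; the resulting active fraction on the signal line is ≈ 0.28.

What the generator does **not** emulate: real pharmacophore geometry, 3D
conformations, stereochemistry, correlated assay noise between cell
lines, and activity cliffs unrelated to the planted positions. Passing
tests therefore demonstrate that the pipeline recovers a planted,
descriptor-expressible signal of realistic size from realistically noisy
multi-cell-line data — not that any particular real series will yield
models of the same quality.

## Numerical choices and degenerate inputs

* Round-half-up (`⌊x + 0.5⌋`) for all split sizes; test partitions are
  never empty; singleton clusters train.
* Max–min ties break to the lowest original index; k-means is seeded and
  repairs empty or collapsed clusters by splitting the largest cluster at
  its farthest point.
* PLS: eigenvalues clamped at zero; component extraction stops on
  residual exhaustion relative to the *uncentered* response scale.
* Bayes: probability floor 10^-9 per bin before renormalization;
  log-space likelihood accumulation with max-subtraction; out-of-range
  queries clamp.
* Missing IC50s exclude a compound from that cell line's modeling — never
  imputed.
* IC50 equal to the cutoff is active (boundary convention).
* Byte-identical artifacts across reruns with the same seed; the run
  manifest records versions, seeds, split sizes and every decision
  parameter.

## Problem sizes used by the shipped checks

The test suite and the acceptance script exercise the workflow at the
study's own scale: 93-compound libraries, 60/33 and 61/32 divisions,
25-seed replicates for the stochastic recovery checks, 100 random
libraries (N ≤ 10) for the max–min oracle, and 200 random instances
(≤ 3 descriptors, ≤ 8 compounds) for the brute-force Bayes oracle. These
sizes were chosen as the smallest that exercise every code path at the
emulated study's dimensions.

## Known limitations

* Descriptor values are open analogues, not reproductions of any
  commercial package's numbers; conclusions about descriptor *families*
  transfer, individual values do not.
* The DLI set cannot distinguish which position a substituent occupies;
  on the synthetic series this makes it strictly weaker than the general
  set for the planted signal, which is a property of the generator +
  descriptor pairing, not of the pipeline.
* Canonical molecule keys can in principle collide for isomer pairs that
  differ only in bond-order placement over an automorphic all-single-bond
  skeleton; irrelevant for the shipped fragments.
* No synthetic-accessibility or 3D-feasibility filtering of suggestions;
  single-point mutations only.
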