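# bqsar — binary QSAR workflow with diversity-based division and R-group suggestions

`bqsar` is an R implementation of a complete small-molecule QSAR
(quantitative structure–activity relationship) study design for inhibitor
series assayed against several cell lines. It targets the situation where
cytotoxicity data are too noisy for regression and a *binary* activity
model — active/inactive against a positive-control IC50 cutoff — is the
scientifically appropriate choice, and where the analyst wants concrete,
ranked single-point modification suggestions at the end.

The pipeline covers, end to end:

* **Structure and activity I/O** — SDF (V2000) and SMILES reading
  (ChemmineR/OpenBabel-backed, per-record failure reporting), CSV
  activity tables with strict missing-value conventions.
* **Two descriptor sets** — physicochemical "general" descriptors
  (additive-atomic-contribution logP and molar refractivity, approximate
  van der Waals surface-area partitions, PEOE partial-charge statistics)
  and a topological drug-like index (rings, ring systems, linkers,
  frameworks, side chains).
* **Diversity-based dataset division** — greedy max–min ranking: entry
  #1 is the file's first compound, each next rank goes to the compound
  maximizing its minimum Euclidean distance to everything ranked so far;
  training = first ⌊0.65·N + 0.5⌋ entries (60/33 for N = 93). A
  cluster-then-diversify variant runs the same rule per descriptor-space
  cluster (61/32 for the shipped fixture clustering).
* **Four model back-ends** — PLS regression (NIPALS, condition limit
  10^6 on the correlation-matrix principal components, unlimited
  components), ε-insensitive RBF SVR, RBF SVM, and a **binary Bayesian
  classifier**: per-descriptor class-conditional histograms over a
  [0, 1]-normalized training range (25 bins), convolved with a Gaussian
  of width σ = 0.25, floored and renormalized; naive-Bayes combination
  with class priors; a compound is called active when P(active) > 0.5.
* **Evaluation grids** — R²/Q²/r² for regression, At/Av/Ap (training
  self-fit, leave-one-out, independent test) for classification, per
  cell line and descriptor set; σ columns (drug-like − general); a
  paired t-test comparing the two division schemes cell by cell.
* **A SAReport-style suggestion engine** — scaffold matching (induced
  subgraph isomorphism), R-group decomposition, enumeration of all
  single-point mutations observed elsewhere in the series, scores scaled
  so 0 = "as likely active as an average input molecule", weighted by a
  [0, 1] structural-support factor, ranked by score × weight.
* **A synthetic 93-compound generator** with known ground truth — four
  scaffolds plus six off-scaffold decoys, one descriptor-driven signal
  cell line and three noise-dominated ones — so the whole workflow is
  testable without proprietary data.

See `vignettes/methods.Rmd` for the model details, parameter defaults,
and design rationale.

## Worked example

```r
library(bqsar)

run <- run_pipeline(run_config(seed = 1))
#> [bqsar] library: 93 compounds, 4 cell lines
#> [bqsar] division diverse: train 60 / test 33
#> [bqsar] division cluster_diverse: train 61 / test 32
#> [bqsar] division t-test: t=0.1856 p=0.8531 over 96 pairs
#> [bqsar] top suggestion: demethylation at position 8 (+66.4%)

s <- run$sigma_tables$diverse
s[s$model == "Bayes" & s$metric == "Ap", ]
#>    division model metric cell_line general drug_like   sigma
#> 9   diverse Bayes     Ap    BxPC-3   0.545     0.424 -0.1212
#> 21  diverse Bayes     Ap  NCI-H446   0.879     0.818 -0.0606
#> 33  diverse Bayes     Ap    SW1990   0.455     0.455  0.0000
#> 45  diverse Bayes     Ap  NCI-H157   0.636     0.455 -0.1818

head(run$sar_report, 3)
#>  rank  parent                       mutation  score weight
#>     1 cpd_054    demethylation at position 8 +66.4% [0.56]
#>     2 cpd_089 dehydroxylation at position 11 +70.7% [0.48]
#>     3 cpd_059    demethylation at position 8 +59.8% [0.49]
```

Reading the output: the synthetic library plants its structure–activity
signal on the NCI-H446 analogue, and the binary Bayes model's
independent-test accuracy (Ap = 0.879) stands far above the three
noise-dominated cell lines (0.45–0.64, i.e. coin-flip territory) — the
pipeline recovers which cell line carries signal. The paired t-test
(p = 0.85) shows the two division schemes do not differ meaningfully.
The top suggestion is demethylation at position 8 — removal of the ring
N-methyl group — with a predicted +66% probability-of-activity gain over
the average input compound and a 0.56 structural-support weight, matching
the generator's largest planted coefficient.

The same pipeline runs on your own files:

```r
cfg <- validate_config('{
  "mode": "files",
  "structures": "compounds.sdf",
  "activities": "ic50.csv",
  "cutoffs": {"BxPC-3": 38.11, "NCI-H446": 9.13,
              "SW1990": 61.05, "NCI-H157": 58.33}
}')
run <- run_pipeline(cfg, out_dir = "results/")
```

A thin command-line front end lives at `inst/cli/bqsar.R`
(`generate`, `run`, `suggest`, `report` subcommands).

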