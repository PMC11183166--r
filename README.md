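# morphnet

Individual-level morphological brain-network analysis in R.

Population-covariance morphometry yields one network per cohort;
`morphnet` instead builds **one gray-matter similarity network per
subject**: every parcellation region's voxel-value distribution is
estimated by kernel density estimation, and each pair of regions is
scored by a divergence-based similarity —

* `KLDs(P, Q) = exp(-[KL(P‖Q) + KL(Q‖P)])` (symmetric Kullback–Leibler,
  natural log), or
* `JSDs(P, Q) = 1 − JSD(P, Q)` (Jensen–Shannon, base-2 log),

giving a symmetric N×N matrix in [0, 1] with unit diagonal (N = 116 by
default, 83 as an alternative parcellation). Matrices are binarized over
a sparsity grid S = 0.05–0.40 (step 0.01, 36 thresholds) and summarized
by global metrics (Cp, Lp, γ, λ, σ, Eg, Eloc; γ/λ normalized against
degree-preserving rewired nulls) and nodal metrics (degree, efficiency,
betweenness), each reduced to its area under the curve (AUC) across the
grid. Group inference uses label-permutation tests (10,000 permutations)
with Benjamini–Hochberg FDR over nodal metrics, and the network-based
statistic (primary threshold t = 3.2, 5,000 permutations, maximal
component size null) to localize altered connectivity. Clinical
association uses Pearson partial correlation controlling for age and
sex. A seeded synthetic cohort generator (38 patients vs 38 controls,
community-structured regional distributions, injected effects, clinical
covariates including an HFMSE motor score on the 0–66 scale) makes the
whole pipeline testable without imaging data.

Intended users: neuroimaging researchers analyzing single-subject
structural MRI morphometry, and methodologists who need a tested,
seeded reference implementation of divergence-similarity networks with
permutation/NBS inference.

## Worked example

```r
library(morphnet)

cfg <- cohort_config(n_per_group = 8, n_regions = 10,
                     voxel_range = c(60, 100), n_communities = 3,
                     effect_nodes = c("R001", "R002", "R003"),
                     effect_size = 10, seed = 77)
cohort <- generate_cohort(cfg)

res <- run_pipeline(run_config(
  cohort = cohort, out_dir = "example_out", measure = "KLDs",
  pdf_grid = pdf_grid_spec(n_points = 64), n_null = 0,
  n_perm_global = 500, n_perm_nbs = 200, primary_t = 3.0, seed = 99))

res$significant_nodes
#> [1] "R001" "R002" "R003" "R005"
subset(res$nodal_tests, significant & metric == "degree")
#>          metric region observed_diff p_value p_adjusted significant
#> degree.1 degree   R001     -0.787500   0.000 0.00000000        TRUE
#> degree.2 degree   R002     -0.528125   0.008 0.02666667        TRUE
#> degree.3 degree   R003     -0.481875   0.020 0.05000000        TRUE
#> degree.5 degree   R005      0.502500   0.000 0.00000000        TRUE
```

The three injected effect nodes are recovered: their nodal-degree AUC is
lower in patients (divergence-based similarity falls when a region's
value distribution is displaced, so the region loses edges at every
sparsity threshold), and the permutation p-values survive BH-FDR at
q = 0.05. The pipeline then feeds the significant node set into the two
one-sided NBS runs and the clinical partial-correlation stage. The
output directory contains the per-subject similarity matrices, metric
curves, AUC tables, test results and a JSON manifest recording every
convention and seed. (Values shown were printed by this exact script;
`R005` reaches significance because displacing its three neighbors frees
edges that reroute through it — degree *gains* in untouched regions are
an expected side effect of sparsity-matched thresholding.)

## Layout

* `R/` — cohort generator, similarity networks, graph topology, group
  inference, clinical association, IO and pipeline orchestration.
* `tests/testthat/` — unit, property and acceptance tests, with
  brute-force oracles (Floyd–Warshall metrics, direct divergence
  summation, inverse-correlation-matrix partial correlation).
* `vignettes/morphnet-methods.Rmd` — the model, conventions, generator
  design and known limitations.
* `inst/scripts/morphnet-pipeline.R` — thin CLI (`simulate`, `run-all`).
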