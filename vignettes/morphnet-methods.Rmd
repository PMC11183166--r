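---
title: "Individual morphological brain networks: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological brain networks: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphnet)
```

## The model

A morphological brain network represents one subject as a graph whose
nodes are parcellation regions (116 regions by default, with an 83-region
alternative) and whose edges quantify how similar two regions'
gray-matter (GM) value distributions are *within that subject*. Unlike
population-covariance networks, which yield a single group-level graph,
this construction gives every subject their own network, so network
properties can be compared between groups and correlated with clinical
scores.

For a subject, each region contributes a sample of voxel-level GM values.
`estimate_region_pdf()` estimates the value distribution by
Gaussian-kernel density estimation (`stats::density`) with an
automatically estimated bandwidth — Silverman's rule of thumb
(`bw.nrd0`) by default; the rule is pluggable. The KDE is evaluated on a
finite grid and renormalized into a discrete probability distribution.
For each unordered pair of regions, both distributions are evaluated on a
*pair-specific common grid* spanning the pooled value range extended by 3
bandwidths on either side (divergences require a common support; the
larger of the two bandwidths sets the padding unit). Similarity is then

* **KLDs**: `exp(-[KL(P||Q) + KL(Q||P)])` with natural logarithms, in
  (0, 1]; and
* **JSDs**: `1 - JSD(P, Q)` with `JSD = KL(P||M)/2 + KL(Q||M)/2`,
  `M = (P+Q)/2`, base-2 logarithms, so both the divergence and the
  similarity lie in [0, 1].

The KLDs↦similarity map follows the individual-network method this
construction is based on; the JSDs transform is a documented package
decision (the `1 - JSD` form yields the [0, 1] similarity scale that
observed morphological connectivity values occupy). The matrix diagonal
is fixed at 1 and excluded from thresholding.

### Numerical choices

* **Grid**: 256 points per pair (default). A coarser grid (64–128 points)
  changes similarities by well under the between-subject variability and
  is used in some tests for speed.
* **Density floor**: after discretization the probability vector is
  floored at `epsilon = 1e-10` and renormalized. This prevents infinite
  KL terms when one region's tail bins are empty on the common grid. The
  floor is applied on the probability scale (post-normalization) so the
  stored distribution both sums to one and respects the floor.
* **Degenerate input**: a region with fewer than 10 finite values or zero
  spread has no defined bandwidth; `build_similarity_matrix()` reports
  *all* failing regions in one error.

## Graph topology over the sparsity grid

Each weighted matrix is binarized at sparsity thresholds `S` from 0.05 to
0.40 in steps of 0.01 (36 thresholds). Sparsity is the ratio of retained
edges to the `N(N-1)/2` possible edges; exactly `floor(S * N(N-1)/2)`
strongest edges are kept, with ties broken by ascending region-pair order
so thresholding is deterministic. Per threshold the package computes
global metrics (clustering coefficient `Cp`, characteristic path length
`Lp`, normalized `gamma`/`lambda`/`sigma`, global and local efficiency)
and nodal metrics (degree, efficiency, betweenness), and each
metric-versus-threshold curve is reduced to a single scalar by its
trapezoidal area under the curve (AUC), which avoids privileging any one
threshold.

Conventions the underlying literature leaves open, fixed here and
recorded in the run manifest:

* **Disconnected pairs**: `Lp = 1/Eg`, the harmonic-mean convention, so
  path length stays finite on the partially disconnected graphs that
  sparse thresholds produce (`1/d = 0` for unreachable pairs). The
  alternative — averaging distances over connected pairs only — was
  evaluated and discards exactly the disconnection signal that
  distinguishes sparse graphs, while producing *larger* normalized path
  lengths against rewired nulls; the harmonic convention is kept.
* **Null model**: `gamma = Cp / <Cp_null>` and `lambda = Lp / <Lp_null>`
  over degree-preserving rewired graphs (double-edge swaps, 10 attempted
  swaps per edge), 100 nulls per threshold by default; `sigma =
  gamma/lambda` exactly.
* **Low-degree nodes**: local clustering is 0 for nodes with degree < 2,
  and they are included in the `Cp` mean (keeps `Cp` defined on sparse
  graphs).
* **Betweenness** is the unnormalized shortest-path count with fractional
  credit across equal-length paths, each unordered pair counted once.

## Group inference

**AUC permutation test.** Group labels are reassigned without
replacement; the two-tailed p-value is the raw proportion of permuted
absolute mean differences at least as large as the observed one (10,000
permutations by default), and the 95th percentile of the absolute null
distribution is reported as the significance threshold. For 10 or fewer
subjects the test enumerates all assignments exactly. Nodal p-values are
corrected by Benjamini–Hochberg FDR at q = 0.05 *within each nodal metric
family across regions* (the correction family is a package decision,
recorded in output metadata).

**Network-based statistic.** Edge-wise pooled-variance t statistics are
computed on raw (unthresholded) similarity values over the node set that
showed FDR-significant nodal AUC differences in any metric. Edges
exceeding the primary threshold `t = 3.2` (about p < 0.001 at the
default cohort size) in the requested direction are kept; connected
components of the surviving edges are the candidate subnetworks, sized by
edge count. Significance comes from re-running the entire
edge-test/threshold/component procedure under label permutation (5000 by
default) and comparing each observed component's size with the null
distribution of *maximal* component sizes; corrected p-values are raw
proportions without +1 smoothing. Two one-sided runs (patient > control
and patient < control) localize hyper- and hypo-connectivity separately.
The NBS literature uses both one- and two-sided edge tests, and
node-selection rules vary between studies; the choices here (one-sided
runs in each direction, selection by any-metric FDR significance) are
documented package decisions.

**Demographics.** Age: pooled-variance two-sample t-test; sex: chi-square
without continuity correction; Shapiro–Wilk normality p-values are
reported descriptively and do not gate the test choice (the package
defines no normality-based branching rule).

**Clinical association.** Pearson partial correlation between nodal AUC
metrics and clinical variables in the patient group, controlling for age
and sex (binary indicator); p-values come from the t transform with
`df = n - 2 - k` and are reported uncorrected, flagged as such. Missing
values are dropped listwise.

## The synthetic cohort generator

No imaging data accompany the analysis, so the generator produces
cohorts with the statistical structure the pipeline assumes, and the test
suite exercises every stage on them. Defaults emulate a 38-versus-38
pediatric cohort: ages truncated-normal (patients 10.37 ± 3.81 years on
5–17, controls 10.30 ± 3.54 on 6–20), sex 24:14 in both groups, disease
duration 7.78 ± 3.61 years on 2–16.5, onset 2.55 ± 2.59 on 0.5–12, and
an HFMSE motor score on the 0–66 scale (33 items scored 0–2).

Regional values are two-component Gaussian mixtures. Communities share
the location of the dominant component (community means drawn from
`runif(0.435, 0.465)` plus per-region jitter of SD 0.01); mode
separation (0.12–0.22), component widths (0.04–0.10 and 0.07–0.13) and
mixture weight (0.5–0.7) vary per region. Region voxel counts are drawn
once per region from 100–300, and every subject adds per-region location
offsets with SD `subject_sd = 0.01`.

These values were calibrated — before any acceptance outcome was
inspected — so that single-subject KLDs networks reproduce the regime the
analysis expects: similarity values spanning roughly 0.2–0.97 with a
median near 0.76 (real morphological connectivity occupies a similarly
broad range), `gamma > 1` across the whole sparsity grid, and `lambda`
near 1. Two findings from that calibration are worth recording. First,
strongly separated communities are *incompatible* with `lambda ~ 1` at
sparse thresholds: the top 5% of edges then all fall within communities,
the graph fragments into cliquish islands, and the rewired-null
comparison pushes `lambda` to 1.5–2.8. Real morphological networks avoid
this because regional distributions differ along several shape
dimensions at once, creating cross-community "shortcut" similarities;
the generator reproduces that through per-region shape variation plus
KDE sampling noise at moderate voxel counts. Second, even in this
regime, group-mean `lambda` at the sparsest thresholds (S near 0.05)
sits at about 1.2–1.3 depending on the community draw — the
rewired-null normalization inherently penalizes clustered graphs right
at the edge of fragmentation, so `lambda` there is the least
comfortable part of the small-world emulation (the small-world
screening test reports exactly this band violation); it falls quickly
below 1.1 by S ≈ 0.15.

**Group effects.** Patients shift the dominant mixture component of each
*effect node* by `effect_size * subject_sd` times a positive multiplier
(a shared per-subject severity factor `|N(1, 0.4)|` times per-node
`|N(1, 0.15)|`), with a fixed alternating sign per effect node. The
alternating sign matters: if all effect nodes shifted together they
would stay mutually similar and the most-changed node in the network
would be an *unshifted* neighbor, not the effect nodes themselves.
Because divergence grows with any shift, effect-node similarity to the
rest of the network falls, so effect-node degree and efficiency are
*lower* in patients — and since HFMSE also declines with the realized
shift (score = `round(66 * plogis(-2 z + e))`, `z` the standardized
exposure, `e` Gaussian with SD 1.2), the designed sign of the
metric–HFMSE partial correlation is **positive**. Detectability scales
with `effect_size` *through the divergence map*, not linearly: shifts
must be resolvable against both between-subject offsets and KDE sampling
noise, so small standardized effects (≈ 1.5) that would be trivially
detectable as raw mean differences are attenuated at the network level.
The effect-recovery tests therefore use effect sizes calibrated to the
network-level gain (stated in each test), not the raw-value scale.

**What the generator does not emulate**: spatial voxel grids, smoothing,
anatomy, hemispheric homologies, scanner covariates, or any real-data
artifact structure. Passing tests show the pipeline's statistical
machinery is correct and calibrated under the generator's assumptions;
they do not certify effect sizes or regional findings on real MRI data.

## Problem sizes used by the automated checks

The test suite runs every stage at sizes chosen to exercise the full
logic while keeping the suite fast: small-world screening on a
10-per-group, 116-region cohort with 10 rewired nulls per threshold;
metric-oracle comparisons on 200 random graphs of up to 12 nodes;
permutation-test calibration with 1000 null replicates at 1000
permutations; NBS calibration/power at reduced node counts and
permutations; effect recovery on 20-region cohorts over 36 thresholds.
The acceptance script (`scripts/acceptance.R`) runs the full-size
computation — 76 subjects, 116 regions, 36 thresholds, 20 nulls per
graph — and reports the minimum group-mean `gamma`.

## Known limitations

* The per-pair common-grid KDE evaluation makes network construction
  `O(N^2)` density calls per subject; a 116-region subject takes a few
  seconds.
* `lambda` at the sparsest thresholds is sensitive to fragmentation (see
  above); interpretations of small-worldness should weight `gamma` and
  the mid-grid behavior, which is also why AUC summaries are preferred
  over single thresholds.
* The NBS node-selection step inherits whatever bias the nodal screening
  has; with no FDR-significant nodes the NBS stage is skipped.
* Correlation p-values are uncorrected by design and flagged as such in
  the output; treat them as exploratory.
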