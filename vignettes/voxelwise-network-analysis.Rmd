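---
title: "Voxel-wise brain network analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise brain network analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxgraph)
```

## The analysis in one paragraph

voxgraph models every gray-matter voxel as a node of a functional brain
graph.  Per subject, multi-run BOLD-like series are nuisance-regressed,
band-pass filtered (0.008–0.08 Hz), z-scored per run and concatenated;
Pearson correlations between all voxel pairs are thresholded to a binary
graph whose density is matched across subjects by fixing
$S = \log(N)/\log(K)$, so that for a given node count $N$ every subject's
network has the same mean degree $K = N^{1/S}$.  Four nodal metrics —
degree, global efficiency, local efficiency, and k-core number — are
mapped back to voxel space.  Group topology is summarized by overlap maps
(the percentage of subjects for whom a voxel ranks in the top 20% of a
metric), group difference maps (flagged above a 25-percentage-point
criterion), and conjunction ROIs over the integration metrics.  Regional
metric means then enter MANOVAs (Pillai's trace), univariate ANOVAs, a
group-by-ROI repeated-measures interaction, hierarchical regressions
against behavior with a dual-density significance rule, and correlations
with life-satisfaction scores.

## Graph construction

**Density matching by edge count.**  Fixing $S$ fixes the edge budget
$M = \mathrm{round}(N \cdot N^{1/S}/2)$.  We match density by keeping the
top-$M$ positive correlations rather than by iterating a correlation
cutoff until $S$ converges: the edge-count route guarantees *identical*
mean degree across subjects exactly, which is the purpose of the
procedure; the correlation cutoff actually used is reported on the graph
object for audit.  Rounding is half-away-from-zero so edge budgets do not
depend on the platform's round-half-to-even rule.

**Sign convention.**  After global-signal regression, correlation
distributions are roughly zero-centered; only positive correlations are
eligible edges ("strongest associations"), and a configuration whose edge
budget cannot be filled by positive pairs is an error suggesting a larger
$S$.  Ties at the $M$-th rank are broken by ascending $(i, j)$ node index,
making edge selection a deterministic function of the correlation matrix.
Zero-variance voxels get undefined correlations, are excluded from
ranking, and remain in the node set as isolated nodes so that maps stay
voxel-aligned.

**Default thresholds.**  $S = 2.5$ and $S = 3.0$ are the two density
levels analyzed throughout; $S$ is also the expected path length of an
Erdős–Rényi graph with the same $N$ and $K$, i.e. the theoretical lower
bound of the network's path length — the package verifies this rationale
numerically (mean finite geodesic of ER graphs at $N = 1000$,
$K = N^{1/2.5}$ is close to 2.5).

## Nodal metrics

Distances are breadth-first-search geodesics, identical to Dijkstra on a
unit-weight graph, implemented in C++ ($O(N \cdot E)$ for all sources).

* **Degree**: edges incident to the node.
* **Global efficiency**:
  $E_{glob}(i) = \frac{1}{N-1}\sum_{j \ne i} 1/d_{ij}$ with $1/\infty = 0$.
  The $1/(N-1)$ normalization is the standard nodal (Latora–Marchiori)
  form, which scales the metric to $[0, 1]$.  Unreachable pairs contribute
  zero — this is exactly why efficiency is preferred over raw path length
  when isolated nodes exist.
* **Local efficiency**: global efficiency inside the subgraph induced by
  the node's direct neighbors (node excluded), i.e. the mean of $1/d$ over
  ordered neighbor pairs with distances measured *within* that subgraph;
  degree < 2 yields 0 rather than an undefined value.
* **Core number**: the largest $k$ such that the node survives iterative
  deletion of all nodes of degree < $k$ (Batagelj–Zaveršnik peeling;
  "network collapse" is the peeling's termination on the empty graph).

All four are cross-checked in the test suite against independent oracles:
Floyd–Warshall distances, brute-force $1/d$ summation, exhaustive
minimum-degree-subgraph membership, and igraph.

## Group topology maps

Per subject and metric, the top 20% of voxels (count
$\mathrm{round}(0.2N)$, ties by node index) defines a binary mask; the
overlap map is the per-voxel percentage of subjects in a group whose mask
contains the voxel, displayed at a 50% threshold.  Difference maps
subtract old-group from young-group overlap and are flagged where the
absolute difference *strictly* exceeds 25 percentage points.  Conjunction
ROIs intersect the flags of the three integration metrics (degree, global
efficiency, core number) in the same direction, then cluster the
surviving voxels under 26-connectivity and drop clusters below 2 voxels.
The clustering rule (26-connectivity, minimum extent 2) is an explicit
package choice: the analysis it reproduces reports conjunction ROIs
without stating its extraction parameters, so both knobs are exposed in
the API.  The difference criterion is applied to raw (unthresholded)
overlap maps.

## Inferential statistics

* **MANOVA**: Pillai's trace $V$ from the between/within SSCP
  eigenproblem with the standard $F$ approximation — exact for two
  groups, where partial $\eta^2 = V$.
* **Univariate ANOVA**: one-way $F$ with $\eta^2 = SS_b/SS_{tot}$.
* **Repeated measures**: split-plot ANOVA with group between subjects and
  ROI within; the interaction $F$ has df $((R-1)(G-1), (R-1)(N-G))$ —
  e.g. $(9, 540)$ for 10 ROIs and 62 subjects — with no sphericity
  correction.  The error-term structure is the standard ROI-by-subject
  within-group stratum.
* **Hierarchical regression**: forced-entry blocks in a stated order
  (group and sex; then the mean-centered regional metric; then the
  group-by-metric interaction), refit by OLS at each cumulative block.
  "Step-wise" here means hierarchical entry, not automatic variable
  selection, because the entry order is enumerated explicitly.  Group (and
  sex) are contrast-coded ±0.5 so the metric's main effect is the
  cross-group average; standardized betas are reported as
  $b \cdot sd(x)/sd(y)$.
* **Dual-threshold rule**: an association counts as statistically
  meaningful only if $p < .05$ at both $S = 2.5$ and $S = 3.0$ *and* the
  effect signs agree; a sign conflict is a warned failure.  No further
  multiple-comparison correction is applied by default.
* **Correlations**: Pearson $r$ with two-tailed $p$ from the $t$
  transform with $n - 2$ df.

Pillai's trace, the ANOVA and the split-plot interaction are computed
from sums of squares directly and verified against `stats::manova` and
`stats::aov` to $10^{-8}$ on shared fixtures; calibration tests confirm
empirical type-I error near the nominal 5% under permuted group labels.

## The synthetic cohort generator

The generator is a first-class module, not a fixture: it defines the
study conditions under which the pipeline is validated.

**Acquisition geometry.**  Three runs of 150/220/180 time points at
TR = 1.5 s (550 concatenated volumes), a 12×12×12 voxel grid (1,728
nodes) tiled into 4×4×4 modules.  Larger grids are supported; the test
suite uses the 12³ default.

**Signal model.**  Each voxel is a unit-variance factor mixture: its
module factor (squared loading = the within-module correlation), optional
cross-community loadings, an optional long-range pair factor, and white
residual noise.  Because the covariance is an explicit factor
decomposition $LL^\top + D$ it is positive semi-definite by construction;
configurations whose per-node squared-loading budget exceeds 0.98 are
rejected with a parameterization error.  Factors are white in time —
band-pass filtering then removes variance but leaves correlations
unbiased.  Temporal autocorrelation of the hemodynamic response is *not*
modeled; the generator validates correlation-graph topology, not spectral
realism.

**Community architecture.**  One DMN-like module (young within-module
correlation 0.42, old 0.15 — the planted integration loss), one SAL-like
module acting as the hub set (young 0.22; old 0.38 plus a squared loading
of 0.49 onto the strongest background module, i.e. hub-to-target
correlations ≈ 0.41 — the planted integration gain), one FP-like module,
and two background tiers: a "high" tier of strongly coherent modules
(within 0.34) sized so that one planted community plus the high tier just
fills the top 20% of nodes, and a weakly coherent "sea" (within 0.16).
The two-tier background makes top-fraction membership of background
voxels essentially deterministic, which keeps spurious between-group
overlap differences rare; a smooth gradient of module coherence was tried
first and produced unacceptable boundary noise (many modules sat within
sampling error of the top-20% cut, and group-specific edge budgets moved
the cut between groups).  Two always-on wiring layers keep the graph
connected without group differences: a long-range backbone (one matched
pair per non-planted voxel at correlation 0.32) and a DMN bridge (each
DMN voxel paired with a dedicated sea voxel at 0.45, identical in both
groups, so the DMN clique reaches the giant component at both density
levels).  Both planted communities have equal size (one module each), so
the fixed-count top-20% selection displaces the same number of background
slots in both groups.

**Nuisance components.**  A global signal (amplitude 0.25, mildly
heterogeneous across voxels), six AR(1)-smoothed motion regressors whose
voxel-wise coupling scales with the subject's motion covariate, and an
optional 0.025 Hz "task bump" (off by default) confined to the FP-like
module for PSD QC.  The per-run nuisance design (intercept, global,
six motion columns) is stored with the data, and the preprocessing stage
removes what the generator injected.  The motion covariate is drawn from
group-specific lognormals with means 0.0975 mm (young) and 0.0902 mm
(old) — the motion-matched configuration — rather than simulating
realignment.

**Behavior.**  Subject-level standard-normal latents modulate the
DMN-like and SAL-like coherence; behavior couples to those latents.
Single-task RT is a linear function of the DMN latent with planted
standardized coefficient −0.4; task-switching trials are generated around
subject-level local (≈250 ms) and global (≈300 ms) costs so the scoring
operations recover them; SWLS totals (old group only, mean 26.2, SD 5.5)
couple to the SAL latent at a target correlation of 0.5 and are
decomposed into five 1–7 items that re-sum exactly.  The spatial
working-memory composite is defined as the average of z-scored accuracy
and negated z-scored mean RT, cohort-standardized to unit SD — the
instrument defines no composite formula, so this package choice is
recorded in the result's metadata.

**What passing tests do and do not show.**  The generator emulates the
statistical properties the analysis assumes (modular correlation
structure, density-matchable correlation distributions, planted effects
larger than sampling noise at n = 15 per group).  It does not emulate
hemodynamics, spatial smoothness of real BOLD noise, registration error,
or realistic motion artifacts, so recovery results certify the pipeline's
correctness and sensitivity under its own model — not performance on real
fMRI.

## Numerical choices and degenerate inputs

* Band-pass is an ideal FFT-domain filter (open interval, DC always
  removed); no filter design is claimed by the source procedure, and edge
  effects of the ideal filter are accepted and documented.  Pipeline
  order is regression → band-pass → per-run z-scoring → concatenation,
  fixed and recorded in the output's provenance attribute.
* Masking uses the linear-interpolation (type-7) percentile with ties at
  the threshold included; node order is the x-fastest raster over in-mask
  voxels, and `unmask()` inverts it exactly.
* Seed-connectivity z maps use the Fisher-z normal approximation
  $z = \operatorname{atanh}(r)\sqrt{T-3}$; degenerate $|r| = 1$ is capped
  at $\operatorname{atanh}(1 - 10^{-7})\sqrt{T-3}$ and the cap is
  reported.  This is a QC surrogate, not a registered group GLM.
* All-equal metric maps trigger a degenerate-map warning and fall back to
  index order; empty conjunctions warn and return an empty ROI set.
* Every stage of `run_pipeline()` is cached under a hash of its own
  parameters chained with its upstream hash: identical config and seed
  reproduce byte-identical result tables, and changing only the S levels
  reruns the network stage onward.

## Problem sizes used by the test suite

The validation suite runs the full design at its native scale — 12³ grid,
15 + 15 subjects, both S levels — once, plus a 6³-grid toy pipeline for
caching/determinism checks, 100-subject Monte-Carlo runs for correlation
recovery, 500 label permutations per calibration test, and 200–500
replicates for effect-recovery checks.  These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays convenient to run on a laptop.

## Known limitations

* Down-sampling to a coarser analysis grid and registration to a
  template are out of scope; node resolution is whatever grid the input
  provides.
* Whether nuisance regression preceded or followed band-pass in the
  reproduced pipeline is not documented; the order above is fixed and
  logged.
* Weighted graphs, negative-edge networks, modularity detection,
  clustering coefficient and characteristic path length are deliberately
  not implemented (efficiency metrics replace the latter two).
* The MANOVA enters each metric separately (global and local efficiency
  are not tested jointly), mirroring how the reproduced analysis reads.
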