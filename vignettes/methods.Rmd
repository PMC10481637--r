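---
title: "Composite health-inequality indices and their spatial analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite health-inequality indices and their spatial analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthineq)
```

## The problem

Health inequalities between small administrative regions (districts, LAU1
units) arise from many determinants of very different nature — economic,
educational, demographic, environmental — alongside the population's health
condition itself. `healthineq` turns a panel of regional indicators,
observed at two (or more) time periods and organized into determinant
categories `A.1`–`A.7` plus a health-condition category `B.1`, into
comparable composite indices, and then asks where the burden concentrates:
how categories correlate with each other and with health condition, whether
individual determinants changed over time, which groups of regions share an
inequality signature, and whether disadvantage clusters in space.

## The weighted-sum (WSA) index model

Each indicator $j$ is a criterion with an optimization direction. With
$A_j^+$ and $A_j^-$ the best ("ideal") and worst ("basal") observed values,
raw values $y_{ij}$ are min-max normalized to $r_{ij} \in [0,1]$:

$$r_{ij} = \frac{y_{ij} - A_j^-}{A_j^+ - A_j^-} \quad\text{(maximize)},
\qquad
r_{ij} = \frac{A_j^+ - y_{ij}}{A_j^+ - A_j^-} \quad\text{(minimize)},$$

so that after normalization every criterion reads "higher is better". A
region $a_i$ scores the utility

$$u(a_i) = \sum_{j=1}^{k} v_j\, r_{ij}, \qquad \sum_j v_j = 1,\; v_j > 0,$$

with equal weights $v_j = 1/k$ throughout. Phase 1 scores each category
separately (giving seven determinant indices and the `B.1` health-condition
index); phase 2 scores all determinant indicators together, giving the
aggregate index. All indices live in $[0,1]$; a region attaining every ideal
scores exactly 1.

Assumptions worth stating: utilities are linear in the normalized values
(no diminishing returns), criteria are substitutable (a good score on one
indicator can offset a bad one), and the observed extremes define the
meaningful range. These are the standard, deliberately simple assumptions
of weighted-sum multi-criteria scoring.

### Key parameter choices

* **Bounds scope** (`bounds_scope`): ideal/basal values are pooled across
  periods by default. Index *levels* are then comparable over time, which
  the temporal comparisons (mean/median differences, decline counts)
  require. Per-period bounds are available (`"per_period"`) but make
  levels period-relative.
* **Aggregate mode** (`aggregate_mode`): the default weights all
  determinant indicators equally (`1/33` with the default panel), reading
  "all categories together with equal weights" at the indicator level. The
  alternative `"mean_of_categories"` averages the seven category indices
  instead; the two coincide exactly when all categories are equally sized.
  Both are exposed because either reading is defensible.
* **Degenerate bounds**: a constant indicator carries no information; it is
  normalized to the neutral value 0.5 with a warning rather than dropped,
  which keeps $k$ and the weights stable across periods and regions.
* **Precision**: indices are computed and stored at full precision;
  rounding (2 decimals for indices and correlations, 1 for shares) happens
  only in the report writers of `run_pipeline()`.

## Association statistics

Pairwise Pearson correlations among category indices (optionally including
`B.1`) describe the dependency structure per period. Temporal change of
each determinant is tested with the **paired Wilcoxon signed-rank test** on
raw indicator values — the same regions observed at two times are natural
pairs, and raw values avoid any interaction with the normalization. Zero
differences are dropped (the classical treatment); the exact two-sided
p-value enumerates all $2^n$ sign assignments via the convolution of the
rank distribution (used up to $n_\text{effective} = 25$ without ties, where
it is both exact and fast); otherwise a normal approximation with
tie-corrected variance and no continuity correction is used. No
multiple-testing adjustment is applied by default, matching a raw 0.05
reporting threshold per determinant; Benjamini–Hochberg is available via
`adjust = "BH"`.

## Clustering regions by inequality signature

Regions are clustered on their seven category-index profiles with **Ward's
method** on squared Euclidean distances, implemented via the Lance–Williams
recurrence with the merge height recorded as the Ward cost increase and
ties broken by the lexicographically smallest pair of cluster indices, so
runs are reproducible bit for bit. The seven-dimensional category profile
is the default feature vector rather than the scalar aggregate index: Ward
on a single scalar cannot produce distinct multi-category signatures, which
are precisely what the z-score profiles display. A 1-D mode is available by
passing the aggregate index as the feature.

The tree is cut at $k = 4$ clusters by default and labels are ordered by
descending mean aggregate index, so cluster 1 is the best-off group and
cluster $k$ the most disadvantaged. Features are not re-standardized before
clustering — the indices already share the $[0,1]$ scale — though `zscore()`
can be applied first if desired. Cluster signatures are **population
z-scores** ($1/n$ variance) of each category, averaged within clusters: the
region set is the complete population of districts, not a sample. The
size-weighted mean of cluster mean z-scores is identically zero per
category, so profiles read directly as above/below the national average.

## Spatial analysis

Contiguity weights come from the region polygons under the **queen
criterion** (any shared boundary point, detected by snapped-vertex
matching), row-standardized. Queen contiguity is the conventional default
for irregular administrative polygons. Local spatial association uses
Anselin's **local Moran** statistic

$$I_i = \frac{x_i - \bar x}{m_2} \sum_j w_{ij}\,(x_j - \bar x),
\qquad m_2 = \tfrac1n \sum_k (x_k - \bar x)^2,$$

whose average over regions equals global Moran's I under row-standardized
weights. Inference is by **conditional permutation**: holding $x_i$ fixed,
the remaining values are permuted across the other regions (999 draws by
default) and the pseudo p-value is
$(1 + \#\{|I_i^{\text{perm}}| \ge |I_i^{\text{obs}}|\})/(N+1)$. Because the
observed statistic is exchangeable with its permuted replicates under the
null, this magnitude-based pseudo p-value is discrete-uniform, so a test at
level $\alpha$ rejects a true null at rate $\alpha$ (up to the $1/(N+1)$
grid) — a calibration the test suite verifies empirically. Significant
regions are labelled by quadrant: HH/LL spatial clusters, HL/LH spatial
outliers. Isolate regions (no neighbors) are flagged and excluded.

"High" and "low" index classes for the bivariate maps use exact
**Fisher–Jenks natural breaks** (dynamic programming over sorted values,
deterministic, tied values never split) rather than the iterative heuristic
— determinism makes it testable against the all-partitions brute force. The
bivariate label crosses the top/bottom Jenks classes of two indices
(high-high, high-low, low-low, low-high, middle), with 4 classes per axis
by default; share tables report the percentage of regions per label and
period. Because the class count of the original maps is not recoverable,
share values are reproducible only conditional on that choice.

## The synthetic panel generator

`sample_panel()` emulates the structure the analysis assumes, so the whole
pipeline is testable without any external data: 77 regions on a 7×11 unit
lattice, 33 determinant indicators in seven categories plus 24
health-condition indicators, two periods.

* **Correlation structure**: per-region latent category factors are drawn
  from a multivariate normal whose correlation matrix is the target
  (`default_category_correlation()`): +0.6 between economic status and
  education, −0.45/−0.55 of both with the demographic situation, +0.55 of
  each with health condition, weak links elsewhere. Each indicator loads
  on its category factor with loading 0.8 plus independent noise, then
  receives an indicator-specific affine scale so raw units are
  heterogeneous; minimize-direction indicators (half, by default) are
  sign-flipped through a monotone decreasing map. Note the index-level
  correlations are attenuated relative to the latent targets (the
  indicator noise only partially averages out within a category), which is
  why a latent 0.6 appears empirically near 0.5.
* **Temporal drift**: period 2 adds a per-category latent mean shift (mild
  improvement +0.2 sd for most determinant categories, deterioration for
  the demographic situation and road safety, a slight decline −0.15 sd of
  health condition) plus innovation noise (sd 0.3). Both the latent
  factors and the indicator noise persist across periods — period 2 is
  period 1 plus innovations — so regions keep their relative positions and
  systematic drift is detectable, as in real administrative panels.
* **Spatial structure**: optional iterated moving-average smoothing
  $(1-\rho)z + \rho Wz$ of the latent fields over the queen weights raises
  spatial autocorrelation monotonically in $\rho$; hotspot blocks can be
  planted by shifting every indicator of a block a chosen number of
  standard deviations in the "worse" direction.

What the generator does **not** emulate: non-Gaussian marginals (real
indicators are often skewed or bounded counts), measurement error
correlated across indicators, the mixed reference years inside a period,
and real administrative geometry (the lattice has far more regular
contiguity than Czech districts). Passing tests therefore demonstrate the
pipeline's correctness and calibration under a known, well-behaved
generating process — not that any real panel satisfies those assumptions.

## Validation design and problem sizes

The test suite checks each hand-implemented algorithm against an
independent oracle: Ward linkage against exhaustive minimum-ESS
agglomeration ($n \le 8$) and against `stats::hclust` on squared distances
($n = 40$, tolerance $10^{-9}$); Fisher–Jenks against the all-partitions
brute force ($n \le 20$, $k \le 4$); the exact Wilcoxon p against full
$2^n$ enumeration ($n \le 10$); local Moran against a hand-computed
line-graph case and the global-Moran averaging identity. Statistical
calibration uses 2,000 null replicates of 77 pairs for the Wilcoxon type-I
error and 200 noise fields on a 10×10 lattice (999 permutations) for the
LISA null rate. Parameter recovery plants known structure — correlation
signs at the default panel size, a two-population split of 40 regions
recovered by Ward with adjusted Rand near 1, a 3×3 hotspot on a 12×12
lattice recovered by LISA with sensitivity near 1 over 50 seeds. These
sizes keep the full suite in the minutes range on a single core while
leaving the Monte-Carlo tolerances meaningful.

## Known limitations

* Equal weighting is the only weighting scheme with first-class support;
  `wsa_utility()` accepts arbitrary weights but no elicitation or
  sensitivity machinery is provided.
* Min-max normalization is sensitive to outliers in the observed extremes;
  a single extreme region stretches everyone else's scale.
* Queen contiguity is detected through shared polygon vertices; boundaries
  that touch only between stored vertices (rare in practice, absent in
  lattices) are missed.
* The Wilcoxon exact path refuses nothing but warns with tied absolute
  differences; with heavy ties the normal approximation is the safer
  default and is what `mode = "auto"` selects.
* Composite indices carry no uncertainty intervals; the package treats the
  region set as the full population.
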