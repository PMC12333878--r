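---
title: "Quantifying brain network dynamics with topological and geometric distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brain network dynamics with topological and geometric distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`dfcdist` quantifies how fast a subject's functional brain network
reorganizes over a resting-state scan, and tests whether that rate differs
between diagnostic groups. Regional time series are cut into short sliding
windows; each window yields a connectivity matrix of absolute Pearson
correlations between regions; the distance between consecutive matrices —
measured seven different ways — forms a per-subject *distance series*; each
series is reduced to two scalars (its mean, and the mean of its five largest
values); and group differences in those scalars are tested by sex-stratified,
age-residualized two-tailed permutation tests with Bonferroni correction
across the eight tests run per metric.

```{r, eval = FALSE}
library(dfcdist)
config <- pipeline_config(simulate_from = sim_config(n_per_cell = 4, seed = 1),
                          n_permutations = 5000, seed = 1)
results <- run_pipeline(config)
```

## Dynamic functional connectivity construction

A scan is a $T_{pts} \times M$ matrix of $M$ regional signals sampled every 3
seconds. Scans shorter than 90 or longer than 600 time points are flagged as
excluded (they are reported, never silently dropped). Windows hold $s = 5$
consecutive samples (15 s) and advance by $c = 2$ samples (6 s), so the
window count before trimming is $\lfloor (T_{pts} - s)/c \rfloor + 1$ — 43
windows for a 90-point scan. Within window $i$, connectivity between regions
$j$ and $k$ is the absolute Pearson correlation $|\rho_i^{jk}|$ of their
5-sample segments; the diagonal is zero. Absolute values are used because
both strong positive and strong negative coupling indicate connectivity.

Three trimming rules are applied in a fixed, tested order: (1) trailing
samples that do not fill a complete window are clipped; (2) the first and
last complete windows are removed, because windows at the scan boundaries are
the most exposed to onset/offset artifacts (43 becomes 41); (3) all subjects'
sequences are truncated *from the end* to the cohort minimum so that every
subject contributes equally many transitions. Truncation side is a genuine
free choice — nothing in the design prefers early over late windows — and
end-truncation is the simplest rule consistent with step (1); it is asserted
in the tests so it cannot drift silently.

Degenerate windows (a region constant across all 5 samples) have undefined
correlations; those edges are set to 0 with a warning. This keeps every
matrix valid, and 0 is conservative for all seven distances: it cannot
manufacture spurious change.

## The seven distances

For consecutive connectivity matrices $C_t, C_{t+1}$:

* **Manhattan** $\sum_{i,j} |\Delta_{ij}|$, **Frobenius**
  $(\sum_{i,j} \Delta_{ij}^2)^{1/2}$ and **Chebyshev** $\max_{i,j}
  |\Delta_{ij}|$ are element-wise distances of the difference
  $\Delta = C_t - C_{t+1}$. Sums run over the full matrix, so each undirected
  edge is counted twice. This doubles Manhattan and scales Frobenius by
  $\sqrt 2$ relative to an upper-triangle convention; permutation p-values
  are invariant to any such monotone rescaling, so the convention only
  matters for comparing raw distance values, and it is pinned by tests.
* **Nuclear** is the sum of singular values of $\Delta$ (sensitive to
  low-rank, pattern-level change) and **spectral** is the Euclidean norm of
  the difference between the two sorted eigenvalue spectra (sensitive to
  global reorganization). Spectra of symmetric matrices are real; sorting
  ascending makes the pairing well-defined and order-convention-free.
* **Wasserstein (0- and 1-homology)** compare the topology of the two
  weighted graphs through their graph filtrations (below).

Useful inequalities — Chebyshev ≤ Frobenius ≤ Manhattan, Frobenius ≤ nuclear
(Schatten ordering), and spectral ≤ Frobenius (Hoffman–Wielandt) — are
checked on $10^4$ random matrix pairs in the test suite, as is homogeneity
under joint rescaling.

## Persistence of graph filtrations

Thresholding a connectivity matrix at level $\varepsilon$ (keep edges with
weight $> \varepsilon$) and raising $\varepsilon$ produces a nested family of
graphs in which connected components are progressively born and independent
cycles progressively die. For a complete weighted graph on $M$ nodes this
entire persistence structure reduces to two multisets:

* the $M - 1$ **component birth values**, which are exactly the edge weights
  of a maximum spanning tree, and
* the $1 + M(M-3)/2$ **cycle death values**, the remaining off-diagonal
  weights.

For $M = 116$ regions that is 115 births and 6555 deaths. The implementation
runs Kruskal's algorithm with stable index-order tie-breaking; only the
weight multiset is exposed, which is tie-break invariant (matroid exchange),
and the tests verify agreement with a brute-force filtration oracle — one
that literally counts components with `igraph` at every distinct threshold —
on random graphs up to $M = 8$ including heavily tied weights.

Because two matrices on the same region set have equal-cardinality birth (and
death) multisets, the optimal $p$-Wasserstein matching is the sorted
bijection, and the distance is simply the $p$-norm of the sorted-vector
difference. The order $p$ defaults to 2, the convention in the
persistent-homology literature; it is exposed as `wasserstein_order_p`
because nothing in the method forces that choice.

## Summaries and inference

Each distance series (length $T - 1$, i.e. 40 transitions for a trimmed
90-point scan) is reduced to its **mean** — sustained temporal variability —
and its **5-peak average**, the mean of its five largest values — sensitivity
to brief, pronounced disruptions. "Peaks" are the five largest values, not
local maxima of a smoothed curve: that is what the summary's defining formula
computes, and it keeps the statistic free of smoothing parameters. Ties at
the fifth-largest value are resolved by taking exactly five values in stable
order; averaging tied values fractionally would change nothing detectable by
the permutation test, which only consumes the resulting scalar.

Within each sex stratum and diagnostic contrast, age is regressed out of the
pooled two-group summary values by ordinary least squares, once, before
permutation; the residuals are the age-adjusted measures. Pooling the two
groups (rather than fitting controls only) uses all the data to estimate one
age slope and keeps the procedure symmetric in the groups; fitting within
permutations is deliberately avoided so the null distribution is a pure
relabeling of fixed values. The test statistic is $T_{obs} = |\bar x - \bar
y|$; labels are randomly reassigned $B$ times (default 50,000, reduced to 999
in the calibration studies) and $p = B^{-1} \sum_b \mathbf 1\{T^{(b)} \ge
T_{obs}\}$, a two-tailed test. The estimator is used without +1 smoothing, so
$p = 0$ is possible; a `smooth_p` option provides $(1 + \text{count})/(1 +
B)$ for users who need strictly positive p-values. When $\binom{m+n}{m} \le
10{,}000$ the test enumerates all assignments instead and is exact. Sampled
permutations are drawn independently across iterations (distinctness is not
enforced; at these $B$ and group sizes collisions are immaterial and
independent sampling keeps the estimator unbiased).

Significance uses $p \le \alpha/8$ with $\alpha = 0.05$: eight tests per
metric (2 contrasts × 2 sexes × 2 test types), threshold 0.00625
(conventionally displayed as 0.006). The comparison is non-strict, so a
p-value exactly at the threshold is declared significant. Every grid cell
derives its own RNG stream from the root seed and the cell labels, so results
are independent of execution order; a cell with an empty stratum fails with a
recorded message without aborting the rest of the grid.

## What the synthetic cohorts emulate

Real resting-state data cannot ship with the package, so a generative model
stands in for it. Each subject's signal is $k$ smooth latent AR(1) signals
(coefficient 0.8) mixed into $M$ regions through a time-varying mixing matrix
$W_t = W_0 + B_t$ plus white noise, where $B_t$ is a mean-reverting AR(1)
fluctuation (coefficient 0.9, innovation sd 0.3 before scaling) around the
fixed base mixing. Sliding-window correlations of such a signal have genuine
temporal structure, which is the property the pipeline needs.

Group and age effects scale the drift innovations by
$(1 + \text{sustained}_d)(1 + \text{age\_effect}\,(a - \bar a))$. The
mean-reverting form matters: correlation is scale-invariant, so scaling an
unbounded random-walk drift would leave the correlation dynamics essentially
unchanged; anchoring the fluctuation to $W_0$ makes its *relative* amplitude
— and therefore the speed of connectivity change — proportional to the
scale. Transient disruptions are modeled as `n_peak_events` contiguous
intervals (default 10 samples, spanning whole windows at the default window
size) during which a random perturbation of amplitude `peak_effect` is added
to the mixing; they surface as isolated maxima of the distance series, the
signature the 5-peak statistic targets.

Defaults follow the emulated study design where one exists (116 regions,
3-second sampling, scan lengths within 90–600 points, ages ~45–97, three
diagnoses by two sexes). Effect magnitudes have no empirical anchor — the
emulated study reports no effect sizes on any interpretable scale — so the
defaults are zero and the magnitudes used in the calibration studies are
illustrative. The generator deliberately omits hemodynamics, motion, scanner
artifacts and spatial structure; passing tests demonstrate the statistical
machinery is correct and calibrated under exchangeability, not that the
effects resemble any particular clinical population.

## Calibration studies and problem sizes

Two Monte-Carlo studies (reproduced by `analysis/04_calibration.R`, the
acceptance script and the test suite) use a reduced cohort chosen to make
hundreds of replicates affordable while keeping every pipeline stage
non-trivial: two groups of 8 subjects, one sex stratum, 12 regions, 90 time
points, $B = 999$. Group sizes of 8 + 8 also put $\binom{16}{8} = 12{,}870$
above the exhaustive-enumeration cutoff, so the Monte-Carlo branch of the
test is the one being calibrated.

* **Size**: with all effects zero, subjects are exchangeable by construction
  and the rejection rate at $\alpha = 0.05$ over 500 cohorts must lie within
  3 Monte-Carlo standard errors of 0.05 for both test types.
* **Power**: with `peak_effect = 3` in the dementia group and no sustained
  effect, the 5-peak test rejects far more often than the mean-based test —
  three 10-sample disruptions contribute a handful of large transitions out
  of 40, which a mean dilutes but a top-5 average captures.
* **Age confounding**: with an age-dependent drift and disjoint group age
  ranges but no group effect, skipping residualization inflates the type-I
  error several-fold while the residualized test shows none (with fully
  confounded ages it is conservative, since the age fit absorbs part of any
  group difference — the expected cost of adjusting for a perfectly
  confounded covariate).

## Numerical and degenerate-input choices

* Correlations are clipped into $[0, 1]$ after `abs()` to absorb
  floating-point overshoot; zero-variance regions produce 0-edges with a
  warning; windows need at least 3 samples.
* The observed permutation statistic is computed through the same arithmetic
  path as the permuted statistics, so the identity relabeling always counts
  as at least as extreme and exhaustive p-values are exactly the enumerated
  fractions.
* Maximum-spanning-tree ties are broken by stable edge index; only the
  (tie-invariant) weight multiset leaves the function.
* Age residualization refuses constant ages and fewer than 3 subjects;
  `harmonize_lengths` refuses targets longer than the shortest sequence,
  naming the offending subject.

## Known limitations

Pearson correlation captures only linear coupling; the window length (5
samples) makes individual correlation estimates extremely noisy, which is
intrinsic to short-window dFC rather than to this implementation; the
generator's effects are illustrative, so absolute power numbers do not
transfer to real cohorts; and p-values from $B$ samples have granularity
$1/B$, which matters when comparing against thresholds as small as 0.00625 —
use larger $B$ (the 50,000 default) for decision-grade runs.
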