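---
title: "Methods: exhaustive ENM calibration, selection and transfer in nichecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exhaustive ENM calibration, selection and transfer in nichecal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecal)
```

`nichecal` implements an exhaustive calibration workflow for ecological
niche models (ENMs): a grid of candidate Maxent-style models is fitted,
filtered hierarchically by significance, predictive performance and
complexity, and the survivors are refitted, transferred and audited for
extrapolation risk. This vignette is the package's account of the science:
the model, its estimation, the statistics used for selection, the simulator
behind the test suite, and the numerical and design choices a maintainer
should know about.

## The model engine

### Gibbs density and output transforms

The engine estimates a Gibbs (maximum-entropy) density over the cells of the
calibration region M. With feature vector $f(x)$ of the environmental
conditions in a cell and coefficients $\lambda$, the raw output is

$$ q(x) = \frac{\exp(\lambda \cdot f(x))}{Z}, \qquad
   Z = \sum_{x \in M} \exp(\lambda \cdot f(x)), $$

so raw values sum to one over the calibration cells (a unit test asserts
this to $10^{-8}$ on every fitted model). Two bounded monotone transforms
are derived from the entropy $H$ of the raw distribution: the logistic
output $e^{H} q / (1 + e^{H} q)$ and the complementary log-log output
$1 - \exp(-e^{H} q)$. All three outputs are strictly increasing transforms
of one another, so cell rankings — and therefore rank-based statistics —
agree across outputs. Omission thresholds and partial ROC are computed on
the logistic output, the package's default (as in common Maxent practice;
configurable).

### Features

Each variable is first rescaled to $[0,1]$ by its calibration range
(minimum/maximum over unmasked M cells). The feature families are the
classical Maxent classes: linear ($z$), quadratic ($z^2$), product
($z_i z_j$ for all pairs), threshold (step functions $\mathbf{1}(z > k)$)
and hinge (forward $\max(0, (z-k)/(1-k))$ and reverse $\max(0, (k-z)/k)$
ramps). Threshold and hinge knots are placed at evenly spaced positions on
the rescaled range — 25 per variable (per direction for hinges) by default —
rather than at data quantiles. Fixed knots make the basis deterministic and
independent of the presence sample, which buys exact reproducibility and
stable bootstrap replicates at a small cost in adaptivity.

### Estimation and the regularization scale

Coefficients minimize the penalized objective

$$ -\frac{1}{m}\sum_{i=1}^{m} \log q(x_i) \; + \;
   \sum_j \beta_j |\lambda_j|, \qquad
   \beta_j = \mathrm{rm} \times \mathrm{base}(\mathrm{class}, m) \times s_j, $$

where $m$ is the number of (deduplicated, one per cell) presences, $s_j$ the
feature's standard deviation over presences, rm the user's regularization
multiplier, and base(class, $m$) the class-dependent table interpolated on
$m$ (linear/quadratic: 1.0 at $m=10$ to 0.05 at $m\ge100$; product: 2.6 at 0
to 1.4 at $m\ge17$; threshold: 2.0 to 1.0; hinge: 0.5). The convex problem
is solved through the standard equivalence with a weighted L1-penalized
logistic regression of presences against background (background weight 100),
using `glmnet` as the coordinate-descent solver (tolerance $10^{-7}$, at
most $10^4$ passes); presences are also background members, and the lasso
path ends at the penalty scale above, yielding exact zeros. The parameter
count used for AICc is the number of nonzero coefficients.

One scale choice deserves emphasis: the penalty $\beta_j$ applies to the
*mean* presence log-likelihood without the $1/\sqrt{m}$ attenuation that
Maxent's published objective carries. This is deliberately the stronger
convention: it makes shrinkage behavior independent of sample size in the
regime that matters for model selection, and it is the convention under
which a signal-free presence sample (drawn uniformly from the background) is
shrunk to a numerically uniform model at rm = 1 — a property the test suite
checks. Consequences: fitted models are somewhat sparser than Maxent.jar's
at the same rm, and no numeric equality with Maxent.jar is claimed — the
engine is structurally equivalent (same features, same penalty structure,
same output transforms), not bit-compatible.

### Background

The background is every unmasked calibration cell when there are at most
10,000, otherwise a seeded uniform sample of 10,000 (Maxent's convention).
The normalization constant and entropy always refer to the background the
model was fitted on.

### Extrapolation regimes

Transfers evaluate the fitted features on the transfer stack G under three
regimes. *Free*: rescaled values are used as-is, so features extend their
trends beyond $[0,1]$. *Clamping*: each variable is clipped to its
calibration range first, freezing the response at the calibration-boundary
level. *No extrapolation*: as clamping, but any cell with at least one
variable outside its calibration range is set to exactly 0. When G equals M
the three regimes coincide — a contract the tests assert — and the cells
where clamping and no-extrapolation differ are exactly the
strict-extrapolation cells flagged by the per-variable range rule.

## Selection statistics

### Partial ROC

Full ROC AUC is inappropriate for presence-background models, so
significance uses the partial ROC AUC-ratio test. Thresholds are up to
1,000 evenly spaced quantiles of the prediction surface. For each
bootstrap iteration, 50% of the test points are resampled with replacement;
sensitivity at a threshold is the fraction of resampled test suitabilities
at or above it, and the proportional area is the fraction of cells at or
above it. Restricted to thresholds with sensitivity $\ge 1 - E/100$, the
AUC ratio is the trapezoidal area of the sensitivity-vs-area curve divided
by the area of the identity line over the same area range; the reported
p-value is the direct count of iterations with ratio $\le 1$ (iterations
whose restricted region is degenerate count against significance). Defaults
follow standard practice: 500 iterations, 50% bootstrap, $E = 5$.

A known small-sample caveat, inherited from the method itself: with few test
records the restricted region holds only $\approx n_{test} E/100$ points
(2.5 points at $n_{test}=50$, $E=5$), and the direct-count p is
anti-conservative — under a null (uniform) model its false-positive rate at
0.05 can reach ~0.35. The property test for null calibration therefore uses
$n_{test}=300$, where the measured false-positive rate is ~0.03. Users with
small test sets should read pROC significance as evidence, not as a
calibrated error rate; the mean AUC ratio remains centered at 1 under the
null for any $n_{test}$.

### Omission rate

The suitability threshold is the nearest-rank $E$-th percentile of the
training-occurrence suitabilities (rank $\lceil E/100 \cdot n \rceil$; rank
0 maps to the minimum). The omission rate is the fraction of test
suitabilities strictly below the threshold — ties count as predicted, which
makes the statistic deterministic under the discrete suitability values a
grid produces. Omission is non-decreasing in $E$ (property-tested).

### AICc

Model complexity uses the Warren–Seifert convention: the raw output of the
model fitted on the *complete* occurrence set, defensively renormalized over
its unmasked cells, scored at the deduplicated occurrence cells:
$\log L = \sum_i \ln q(x_i)$ and
$\mathrm{AICc} = 2k - 2\log L + 2k(k+1)/(n-k-1)$ with $k$ the nonzero
coefficient count and $n$ the occurrence-cell count. When $n - k - 1 \le 0$
the AICc is undefined: the candidate is recorded, may pass the significance
and omission stages, but is excluded from the Δ/weight stage. Akaike
weights are $w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$.

### Three-stage selection

Selection applies, in order of priority: (1) significance ($p < \alpha$,
default 0.05 — the conventional level); (2) omission rate $\le E/100$ among
the significant candidates — if none qualifies, the significant candidates
with minimal omission are carried forward and flagged as a fallback; (3)
$\Delta \mathrm{AICc} \le 2$, where Δ is recomputed *within* the surviving
set relative to its own minimum AICc. Using the pool-internal minimum
rather than the global one matters: an overfit or non-significant model may
hold the global AICc minimum, and referencing it would empty the selection
for the wrong reason. Selected sets are always nested within the earlier
stages (property-tested on random evaluation tables against an independent
brute-force implementation of the rule).

## The virtual-species simulator

The simulator exists so that every stage of the pipeline is testable without
external data, with a known truth to recover. Its defaults define the
package's reference study conditions:

- **Landscape**: 64 × 64 cells, 3 environmental layers; each layer is seeded
  white noise smoothed with a Gaussian kernel of radius 5 cells (reflective
  padding) and rescaled to $[0,1]$. Radius 5 produces lag-1 spatial
  autocorrelation above 0.5, emulating the smoothness of interpolated
  climate surfaces; radius 0 gives white noise (both property-tested).
- **True niche**: logistic in linear and quadratic terms,
  $\mathrm{logit}(s) = -27 + \sum_i (40 x_i - 40 x_i^2)$ — a unimodal
  response optimal at 0.5 on every variable, giving landscape prevalence
  ≈ 0.2–0.4 depending on the landscape draw. The curvature was chosen once
  so that the species is selective (a near-ubiquitous species leaves no
  signal to recover; extreme rarity starves the sample); typical
  virtual-species studies use comparable prevalences.
- **Sampling**: 200 presence cells drawn without replacement with
  probability proportional to true suitability, coordinates at cell
  centers; split 50/50 into training and testing; 20 independent records
  drawn from the remaining cells. An optional detection-noise rate
  relocates a fraction of presences to random cells for robustness tests.
- **Transfer scenarios**: per scenario, all M layers shifted additively —
  offset 0 (`current`) reproduces M exactly; offset 0.25 (`future`) pushes
  ~18% of cells outside at least one calibration range, exercising
  clamping, zeroing and the MOP/MESS strict-extrapolation rules at a
  nontrivial but not overwhelming rate.

What passing tests on this fixture do *not* show: robustness to sampling
bias, to spatially autocorrelated errors between train and test splits, to
correlated predictors at realistic strengths, or to niche shapes outside
the linear–quadratic family. The simulator emulates geometry and sampling
proportionality, not the full messiness of occurrence data.

## Extrapolation-risk surfaces

**MOP** measures, for every transfer cell, the mean Euclidean environmental
distance (raw variable units by default; optional z-scoring by M statistics)
to its nearest $p\%$ of calibration conditions ($p = 5$ by default;
$p = 100$ reduces to the mean distance to all of M). Distances are converted
to similarities by $1 - d/d_{\max}$, with $d_{\max}$ the maximum distance
over non-strict cells; cells with any variable outside the full M range are
*strict extrapolation* and are pinned to similarity 0. M may be subsampled
(seeded, default cap 10,000 rows) for tractability — the strict range rule
always uses the full M set. **MESS** is included for comparison with the
percentile-based classic: per variable, similarity derived from the
fraction of M values below the cell's value, negative exactly when the
value lies outside the M range; the cell score is the minimum over
variables. The two metrics' extrapolation calls agree by construction
(strict MOP mask ⇔ negative MESS), which the tests assert cell-wise; they
differ in how they grade non-novel cells, where MOP's nearest-neighbor
geometry respects irregular calibration clouds better than MESS's
percentile geometry.

Both accept exhaustive brute-force oracles on small fixtures (all-pairs
distances; direct formula evaluation), which the test suite runs on randomly
generated M/G sets.

## Numerical and design choices

- **Raster format**: ESRI ASCII grids only, written with 6 significant
  digits; the reader accepts corner and center origin conventions. The
  format is text, diffable, and round-trips to $10^{-6}$.
- **Cell assignment**: points belong to the containing cell via
  `floor((coord - origin)/cellsize)`; points on shared edges belong to the
  east/south neighbor (half-open cells). Deterministic, standard raster
  semantics.
- **Duplicates**: occurrence records in the same cell are deduplicated for
  fitting and for AICc (one presence per cell) but retained for evaluation
  statistics.
- **Median consolidation**: replicate and multi-model consolidation is the
  cell-wise median (mean of the two central values for even counts); a cell
  masked in any replicate is masked in the output.
- **Seeds**: every stochastic step consumes a seed derived from the run
  seed plus a stage label, so identical configurations reproduce identical
  CSV outputs byte for byte (tested), and stages can be rerun in isolation.
- **Fault isolation**: candidate fitting and batched MOP never abort on a
  single failure; failures are recorded per item in the batch logs and the
  run log, and results are written to disk as they are produced.
- **Problem sizes in the test suite**: the reference fixture is 64 × 64 × 3
  layers with 200 presences; pipeline tests calibrate reduced grids (2
  regularization values × 3 feature combinations) and 10 bootstrap
  replicates — large enough to exercise every code path and the selection
  logic, small enough to keep the suite fast on one CPU.

## Known limitations

- No categorical features, no reprojection between coordinate systems, no
  GeoTIFF I/O, no cross-validation schemes beyond bootstrap replicates.
- The engine is not numerically interchangeable with Maxent.jar (see the
  regularization-scale note above); comparisons across software should be
  made on predictions and selection outcomes, not coefficients.
- Partial-ROC p-values are anti-conservative for small test samples (see
  above).
- MOP distances in raw units are scale-sensitive when variables have very
  different magnitudes; use the z-scoring option in that situation.
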