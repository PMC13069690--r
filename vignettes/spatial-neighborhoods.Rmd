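---
title: "Boundary-aware spatial neighborhood analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary-aware spatial neighborhood analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatring)
```

# The problem

High-resolution spatial transcriptomics platforms (Xenium, MERFISH, Visium
HD) measure gene expression for individual cells together with their spatial
coordinates. Most differential expression machinery ignores the geometry:
cells are compared by cluster label, not by where they sit relative to
tissue structure. Yet much of the interesting biology happens at
*interfaces* — the rim of a tumor, the cortex/white-matter boundary, the
periportal-to-pericentral axis of a liver lobule. `spatring` makes the local
geometry a first-class covariate: it detects the spatial boundary of a cell
population, defines its neighborhood, converts distance-to-structure into a
per-cell weight, and feeds that weight into moderated linear models and an
enrichment index.

All analysis operates on two inputs: a coordinate table (`cell`, `x`, `y`,
`cluster`; platform length units, planar Euclidean geometry, no unit
conversion) and a normalized log-scale gene-by-cell expression matrix.
Normalization is assumed done upstream; the package validates
non-negativity and does nothing else to the values.

# Boundary detection

For a chosen cluster the pipeline is:

1. **Outlier removal.** For each cell $c$, the mean Euclidean distance
   $\bar d_c$ to its $k$ nearest neighbors is computed ($k$ = `k_outlier`,
   default 5, self excluded, ties broken by ascending cell index so output
   is bit-reproducible). Cells with $\bar d_c > \tau$ are dropped. $\tau$ is
   in coordinate units and should reflect the platform's typical cell
   spacing; there is deliberately no default because it is scale-dependent.
2. **Subregion detection.** A cluster may occupy disjoint patches. DBSCAN
   (default; `eps` in coordinate units, `min_pts = 5`, noise labeled −1 and
   excluded) or k-means (fixed seed, default 0) assigns each retained cell
   to a patch. `min_pts = 5` mirrors the outlier-removal $k$; the paper-free
   choice is documented here once and not tuned per dataset.
3. **Concave hull.** Each patch gets a closed, simple, counterclockwise
   polygon from a concavity-parameterized nearest-neighbor concave hull:
   starting from the convex hull, an edge with squared length $L^2$ is dug
   toward the interior point nearest to it whenever that point's squared
   distance to the closer endpoint is at most $L^2/\text{concavity}^2$ and
   the insertion keeps the boundary simple. `concavity = 2` by default;
   `Inf` reproduces the convex hull, and an optional `length_threshold`
   protects short edges. The construction guarantees every retained point
   ends up inside or on the polygon, which the tests assert at 100%.

Outlier removal runs **once per cluster, before** subregion detection, not
per patch — this keeps $\bar d_c$ comparable across the whole selection and
matches the order in which the stages are defined.

Regions are numbered by descending polygon area, so "region 1" is always
the primary patch. Ring neighborhoods come from buffering a boundary
outward by `dist` (default 100 units) via a Minkowski offset with *round*
joins (mitered joins overshoot at sharp vertices); the ring is the annulus
between the polygon and its buffer. Point-in-polygon tests are
boundary-inclusive — a cell exactly on a detected boundary must not vanish
from both sides — and ring membership is "inside outer AND NOT inside
inner", so the inner region and the ring partition the outer region exactly.

# Spatial weights

Given a reference (a population centroid, a boundary polygon, or one
directional edge of a polygon obtained by splitting at anchor points), each
cell gets:

- a raw distance $d_c$ (to the centroid, or the shortest distance to the
  continuous boundary curve — cells inside the polygon still get a positive
  distance to its outline, because the weight indexes proximity to the
  outline itself);
- a min-max normalized distance
  $\tilde d_c = (d_c - \min d)/(\max d - \min d) \in [0, 1]$, computed over
  whatever cell selection was passed in (callers choose the normalization
  scope);
- a weight from one of four decay kernels:
  inverse $1/(1+\tilde d)$, Gaussian $\exp(-\tilde d^2/2\sigma^2)$,
  linear $1-\tilde d$, quadratic $(1-\tilde d)^2$.

All kernels give weight 1 at distance 0; the inverse kernel has range
$[0.5, 1]$. The Gaussian $\sigma$ defaults to 0.3, putting the half-weight
point near $\tilde d \approx 0.35$ so the kernel decays visibly across the
unit range. When all raw distances are equal (a symmetric ring of cells
around its centroid, say) the spread is zero; rather than erroring, all
normalized distances are set to 0 and all weights to 1. The equality test
uses a relative spread tolerance of $10^{-12}$ so floating-point jitter in
symmetric configurations is not inflated to the full unit range.

# Interaction matrices

`compute_interaction_matrix` counts, for each ordered cluster pair
$(i, j)$, how often cells of cluster $i$ have a cluster-$j$ cell among
their $k$ nearest neighbors (default $k = 10$, self excluded). Each cell
contributes exactly $k$ votes, so row $i$ sums to $k\,|\mathcal C_i|$ — a
conservation law the tests check against a brute-force pairwise-sort
oracle. Self-exclusion is deliberate: including a cell in its own
neighborhood would inflate the diagonal by exactly the cluster size and
carries no information. Row scaling (`row_prop` or `row_z`; constant rows
map to zeros) is provided for display; neighbors are always computed over
exactly the table passed in, so restricting to ring-localized cells is done
by passing that subset.

# Differential expression

## Group contrasts

`run_group_de` fits, per gene, $y = \alpha + \beta\,\mathbb 1(\text{group
A})$ by least squares, then moderates the residual variances with the
standard empirical-Bayes log-variance moment matcher: with
$z_g = \log s_g^2$ and $e_g = z_g - \psi(d/2) + \log(d/2)$, the prior
$(d_0, s_0^2)$ solves $\psi'(d_0/2) = \operatorname{var}(e) - \psi'(d/2)$
(inverted by 1-D root finding on $d_0/2$ bracketed in $[10^{-2}, 10^4]$)
and $s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the log
variances show no excess dispersion, $d_0 = \infty$ and every posterior
variance equals $s_0^2$ — note that for identical observed variances $c$
this pooled value is $c\,e^{\log(d/2)-\psi(d/2)}$, slightly above $c$, the
digamma bias correction that any moment-matched fit of this family applies.
The moderated $t$ uses $d_0 + d$ degrees of freedom; `d0 = 0` bypasses
moderation and reproduces the classical pooled two-sample $t$ exactly
(asserted to $10^{-8}$ in the tests). Expression is log-scale upstream, so
the group coefficient is reported directly as the log fold change in the
upstream base, without re-exponentiation. `min_pct` excludes genes detected
(expression $> 0$) in less than that fraction of cells in both groups.
P-values are Benjamini–Hochberg adjusted within the call; there is no
cross-call pooling. `run_marker_de` is one-vs-rest over clusters.

## Gradient testing

`run_spatial_de` asks whether expression varies smoothly along a spatial
covariate $t$ (weights or distances). The design is built once for all
genes:

1. a natural cubic spline basis $X = \mathrm{ns}(t)$ with `df_spline`
   degrees of freedom (default 3; interior knots at equally spaced
   quantiles, linear tails);
2. the augmented block $[t, X]$ is centered against the constant vector;
3. a pivoted QR keeps the first `df_spline` orthonormal columns, with a
   rank tolerance of $10^{-10}$ relative to the largest $R$ diagonal.
   Because a natural spline already spans the linear trend, $[1, t, X]$ is
   rank-deficient by construction and the pivoted QR is what reduces it to
   exactly `df_spline` independent directions;
4. the first column $Z_1$ is sign-flipped if needed so it correlates
   positively with $t$.

The model is fitted *with* an explicit intercept, $y = \alpha + Z\beta$:
$Z \perp \mathbf 1$ by construction, so $\alpha$ absorbs the mean without
affecting $\beta$, and centered regressors need the intercept for unbiased
fitting. Since $Z^\top Z = I$, the moderated $F$ over the coefficients is
simply $(\sum_j \beta_j^2/k)/\tilde s^2$ on $(k, d_0 + d)$ degrees of
freedom. The test is a *joint* F across all spline coefficients (the
conservative reading of "testing across all coefficients"); per-coefficient
moderated $t$ values are exposed as auxiliary columns for users who want
them. The sign of $\beta_{1}$ ("Z1") is the reported trend direction.
Because knots are quantile-based and the design is centered and
orthonormalized, the statistics are invariant to positive affine transforms
of the covariate — asserted numerically in the tests.

# Spatial enrichment index

$\mathrm{SEI}_g = \sum_c w_c y_{gc} / \sum_c w_c$ is the weighted mean
expression; dividing by the unweighted mean plus $\varepsilon = 10^{-6}$
gives the normalized SEI with baseline 1 under uniform weights. It is a
ranking score, not a test — no p-value is attached. The table is sorted by
normalized SEI descending, ties broken by gene id. SEI is computed over
exactly the cells supplied; population selection is the caller's job.
Companion summaries: Spearman correlation between one gene's expression and
the weights (optionally dropping zero-expression cells first, the
convention used when reading sparse panels; an all-tied vector yields a
flagged `NA`, not an error) and mean expression across equal-width weight
bins (empty bins are `NA`, not zero).

# The synthetic-tissue generator

`generate_tissue` is the test bed's ground truth. It draws coordinates from
one of four layouts (`two_blobs`, `nested_disc`, `half_planes`,
`zones_1d`), assigns cluster labels, and simulates log-scale expression:
markers get `baseline + marker_effect` in their cluster, gradient genes
follow `baseline + gradient_slope * g` (direction +1) or
`baseline + gradient_slope * (1 - g)` (direction −1) where $g \in [0,1]$ is
the layout's normalized spatial covariate, and null genes sit at baseline.
Gaussian noise (`noise_sd`), zero-inflation (`dropout_rate`) and clamping
at zero follow. Defaults, chosen once: baseline 1, marker effect 1,
gradient slope 2, noise 0.5, dropout 0.1 — a signal-to-noise regime typical
of a few hundred cells of in-situ panel data after log normalization.

The generator emulates the *modeling* assumptions (normalized log
expression with additive noise and dropout), not the measurement process:
no transcript counting, no segmentation error, no spatial autocorrelation
in the noise, and layout boundaries are ideal geometric shapes. Passing
tests therefore demonstrate correctness of the algorithms under their own
assumptions, not robustness to the full messiness of real platforms.

Named configurations keep the test suite and examples reproducible:
`small_tissue_config` (400 cells × 60 genes), `medium_tissue_config`
(5 000 × 300), `gradient_bench_config` (400 cells, 50 gradient genes at
signal-to-noise 4 among 950 nulls — used for the power, sign-recovery and
rank-concordance properties), and `null_tissue_config` (200 cells, 1 000
null genes — used for the false-discovery-rate property). These sizes run
the whole suite in well under a minute while leaving the property checks
ample statistical resolution.

# Numerical choices and degenerate inputs

- kNN searches are exact brute-force scans with deterministic tie-breaking
  by cell index; at the selection sizes this package targets, exactness and
  reproducibility beat tree-based speed.
- k-means subregions are seeded explicitly (default 0); DBSCAN is
  deterministic given the input order.
- Buffering uses `polyclip` with an arc tolerance of `dist/200`, which
  keeps round-join areas within a fraction of a percent of the analytic
  Minkowski value.
- Degenerate geometry (fewer than 3 distinct points, collinear input,
  zero-length geometries) raises errors naming the condition; degenerate
  *normalization* (all distances equal) is a defined no-op by design, as is
  the all-zero-variance case in moderation ($d_0 = \infty$, flagged).
- Dense expression files are written with `%.17g`, so write–read round
  trips are exact; all tabular output is TSV with headers, and GeoJSON is
  written at full precision, which is what makes CLI re-runs byte-identical.

# Limitations

Strictly 2-D planar geometry; no geodesic or anisotropic distances; no
count-based models (the expression input must already be normalized); no
spatially correlated noise model in the simulator; no permutation p-values
for interaction enrichment; and the global spatially-variable-gene problem
(SpatialDE/SPARK-style) is explicitly out of scope — the package models
expression against *user-chosen* spatial references, which is a different
question.
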