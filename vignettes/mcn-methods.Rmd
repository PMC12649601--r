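---
title: "Myelin covariance networks: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myelin covariance networks: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnet)
```

This vignette is the package's own account of its science: the statistical
model behind each stage, the parameters that matter (with units and
defaults), what the synthetic-data generator does and does not emulate, and
the numerical choices made where the design was genuinely open. It states
no empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The covariance network model

A myelin covariance network treats the population as the sampling unit: for
every cortical surface vertex `v` we observe one myelin-proxy value
(T1w/T2w ratio, unitless) per subject, and the network edge between
vertices `i` and `j` is the Pearson correlation of those values across
subjects, after confound removal.

**Residualization.** Each vertex is regressed (ordinary least squares) on
the design `[1, age, age², gender, age×gender]` with age in years and
gender coded 0/1 (the coding is a package convention; the underlying model
statement does not fix one). Residuals are observed minus fitted values;
column means are zero by construction of the intercept. Two deliberate
choices:

* Age is **not centered** before squaring, following the stated model
  literally. The price is collinearity risk (e.g. a single-gender cohort
  makes `age×gender` proportional to `age`), which is handled by an
  explicit rank check that names the collinear columns rather than
  silently pivoting them away.
* Zero-variance vertices are an **error, not a drop**: removing vertices
  silently would desynchronize every annotation map downstream.

**Signed strength.** The three per-vertex strength maps sum the negative,
positive, and all off-diagonal correlations. The self-correlation on the
diagonal is structural (always 1) and is excluded, which keeps
`negative ≤ 0` meaningful; entries exactly 0 belong to neither signed
subnetwork. The full map is computed as `positive + negative`, so the
additivity identity holds to the last bit — the same identity that the
published per-class means satisfy at printed precision, which the
acceptance suite checks.

## 2. Gradients: landmark-approximated principal components

The gradient embedding is a **plain centered singular-value
decomposition** of connectivity profiles — the source describes "principal
components", so no affinity kernel, cosine transform, or diffusion-map
α-normalization is applied; this also keeps the full-matrix oracle exact.
For scalability the profiles are correlations against a random landmark
subset (default `min(3000, n_vertices)`, the conventional choice at full
cortical resolution; tests use 10%), so memory scales as
`n_vertices × n_landmarks`.

Conventions, each of which was an open choice:

* **Centering**: each landmark column is centered over vertices — the
  standard principal-component convention with vertices as observations.
  For the full symmetric matrix, row- and column-centering give transposed
  matrices and empirically identical recoveries; the column convention is
  used everywhere.
* **Variance explained**: `d_i² / Σ_j d_j²`, the squared singular value
  over the total variance (squared Frobenius norm) of the centered profile
  matrix. It is non-increasing, sums to at most 1, and is invariant to
  landmark permutation.
* **Sign**: a singular vector's sign is arbitrary; it is fixed by making
  the loading positive at its largest-|loading| landmark. Cross-run or
  cross-method comparisons should still use `align_components()`, which
  reports the sign flip and achieved |r| per component.
* `k` larger than the numerical rank of the centered profiles is an error
  (rank measured against a `max(dim) · eps · d₁` threshold).

## 3. Profiles, decoding and multiple comparisons

* **Class means** are unweighted within each parcel class; the five-class
  cytoarchitectonic convention (agranular, frontal, parietal, polar,
  granular) is the default labeling. **Dispersion across classes is the
  sample standard deviation (n−1)** — this convention is forced by the
  published worked examples: the five printed class means of the first
  gradient give 0.1331 with n−1 and 0.1190 with n, and only the former
  matches the printed value. Classes are units; class size never enters.
* **Term decoding** restricts each term's correlation to the vertices
  where both the input map and that term map are non-zero. A mask below 3
  vertices makes the term undefined: it is excluded from the |r| ranking
  and reported in an attribute instead of contributing a meaningless
  coefficient. Rankings are invariant to monotone rescaling of the input
  only when the rescaling preserves the zero set — a documented caveat,
  since rescaling across zero changes the mask itself.
* **Feature correlations** use the exact t-transform of r with n−2 degrees
  of freedom for two-sided p-values, and flag non-significance iff
  `p > α/m` (Bonferroni), default `α = 0.05` and `m = maps × features`
  (30 in the conventional 3 × 10 design; whether a 6 × 10 family should
  share one correction is ambiguous in the source, so `m` is explicit and
  configurable). Vertices are treated as independent — no spatial
  autocorrelation correction is applied, matching the source convention;
  p-values on spatially smooth real data are therefore optimistic and the
  package makes no claim otherwise.
* **Holm adjustment** is the step-down procedure with monotonicity
  enforcement, implemented directly (and cross-checked against
  `stats::p.adjust` in the tests). The gradient-strength correlation
  matrix uses a Holm family of `k × 3` (9 for three gradients); the family
  size for that analysis is not stated in the source, so 9 is the
  documented default.

## 4. The graphlet landscape

**Thresholding.** Negative cutoffs keep edges with `ρ ≤ t`, positive
cutoffs keep `ρ ≥ t`; `t = 0` is rejected because neither rule covers it.
Isolated vertices stay in the node count. The default cutoff set is
−0.4, −0.2, 0.2, 0.4.

**Catalog.** The 30 classes G0–G29 are *derived*, not hard-coded: the
package enumerates every labeled simple graph on 2–5 nodes, keeps the
connected ones, and collapses them by full-permutation canonical form
(degree sequences are only ever a pre-filter, never a final classifier —
the 4-cycle-with-pendant and the triangle-with-2-path-tail share a degree
sequence but are different classes). The enumeration yields 1, 2, 6 and 21
classes for sizes 2–5. A shipped table then fixes the published
(Pržulj-order) indexing. Positions pinned by the literature and the
analyses this package reproduces — G0 edge, G1 path, G2 triangle, the
4-node order path/claw/cycle/paw/diamond/K4, G9 = 5-path, G10 = fork,
G11 = 4-star, G13 = triangle with 2-path tail, G15 = 5-cycle, G29 = K5,
and the per-class orbit-count structure — are exact. Within a few
equal-size, equal-edge-count groups the published figure leaves the order
ambiguous in text form (G12 vs G14, G17 vs G19, G18 vs G20, G23–G25); the
shipped order there follows the structural reading that the classes
reported frequent in *negative*-threshold (bipartite-like) networks must
be triangle-free, hence G16 = banner and G20 = K2,3 (and indeed the
package reproduces G10/G11/G16/G20 as the negative-threshold leaders on
synthetic data). No quantitative result depends on these slots.

**Exact census.** Connected induced subgraphs are enumerated exactly once
by the ESU algorithm (compiled), and classified by a bitmask lookup built
from the same canonicalization as the catalog. A guardrail aborts above a
configurable subgraph budget (default 5 × 10⁷) and points to the sampler.

**Sampled census.** The sampler is a clean-room lift-and-reweight design,
*not* a reimplementation of any published sampler (whose internals the
source does not give): draw a uniform edge, complete the k-set with
uniform distinct non-endpoints, classify, and weight by the exact inverse
inclusion probability `m · C(n−2, k−2) / e(S)`, where `e(S)` is the edge
count of the induced class. Every connected class contains at least one
edge, so the estimator is unbiased for all 30 classes; 2-node counts are
the edge count exactly. Per-class standard errors come from the binomial
variance of the i.i.d. hit indicator; tests verify unbiasedness against
the exact census, 3-standard-error coverage, and the √2 error shrink under
sample doubling.

**Normalization.** The displayed equation
`f*_Gi = log10(1 + (f_Gi + 1)/Σ_j (f_Gj + 1))` is the default: it is
strictly positive and of the magnitude the published per-class values
print, whereas the prose reading `log10((f+1)/Σ(f+1))` is negative for
every class. Both are available (`formula = "prose"`). All-zero counts
give the forced value `log10(1 + 1/30) ≈ 0.01424` for every class.

## 5. The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws

```
M(s, v) = μ(v) + Σ_k score(s, k) · pattern(k, v)
          + β₁(v)·age + β₂(v)·age² + β₃(v)·gender + β₄(v)·age·gender
          + ε(s, v)
```

with ages uniform on 22–37 years (the age range of the large adult cohort
this stands in for), gender Bernoulli 0/1, a baseline μ around 1.5
(T1w/T2w-ratio scale), and per-vertex confound coefficient maps equal to
smooth random patterns scaled by the `beta_*` amplitudes.

The generator is built so that *recovery tests measure the method, not the
generator's sampling noise*. Four design elements, each adopted after the
naive alternative measurably failed, implement that contract:

1. **Bounded, contrast-shaped patterns.** Planted patterns are smooth
   random vertex maps passed through a bounded sigmoid and then
   orthonormalized. With plain Gaussian smooth maps, a handful of extreme
   vertices dominates the per-vertex signal variance; after Pearson
   standardization this mixes the weaker components and caps their
   recovery near |r| ≈ 0.9 *no matter how small the noise is*. The default
   `pattern_contrast = 0.25` yields bimodal maps (two plateaus with smooth
   transitions) whose signal variance is nearly uniform across vertices.
2. **Variance equalization** (`equalize_variance = TRUE`): heteroscedastic
   noise tops every vertex up to a common total variance, so the planted
   components are *exactly* the principal axes of the population
   correlation matrix. Switch it off for the homoscedastic noise-free
   limits (e.g. the rank-1 ±1 correlation example).
3. **In-sample orthogonal scores**: component scores are mean-zero,
   exactly orthogonal to each other *and to the confound design*, with
   exact standard deviations given by `component_loadings` (default
   1, 0.65, 0.42 — strictly decreasing, spaced so that neighboring
   components do not rotate into each other under landmark subsampling).
4. **Noise projected orthogonal to the planted structure** in-sample.

With all four in place the full-matrix decomposition recovers planted
patterns at |r| > 0.99 and 10% landmarks at |r| > 0.95 across seeds, which
is what the acceptance suite asserts. Orthogonalization consumes k + 5
degrees of freedom of the noise; at the default 200 × 300 scale this is
negligible.

For the higher-order analyses, the relevant world is a *single* planted
gradient with spatially autocorrelated noise
(`noise_smooth_window = 6`, `pattern_contrast = 1`). Two structural facts
make this the right stand-in:

* Under a rank-1 signal, same-sign vertices can never correlate
  negatively, so every negative-threshold graph is bipartite between the
  gradient poles: stars and bicliques (G10, G11, G16, G20) dominate and
  triangles are impossible.
* A rank-1 signal alone produces *multiplicative threshold graphs* on the
  positive side, whose neighborhoods are nested — such graphs contain no
  induced 4-paths at all, so path/triangle dominance there is impossible
  without additional local structure. Real cortical maps have spatial
  autocorrelation; the smoothed-noise option emulates exactly that, and
  with it the positive-threshold networks become band/community-like and
  the path/triangle classes (G9, G13) outrank the star classes. The
  acceptance suite asserts this dissociation as a rank property over ten
  seeds and four thresholds.

**What the generator does not emulate:** cortical geometry (its only
notion of space is vertex order on a ring), scanner bias fields and the
physics upstream of the myelin proxy, non-Gaussian marginals (no
distributional claim about real T1w/T2w values is intended), site or
family structure, and the medial wall. A green test therefore establishes
correctness of the *computations* under a controlled generative model, not
fidelity of any particular empirical claim about real cortices. Headline
empirical quantities from full-scale restricted data (variance-explained
percentages, specific gradient-strength correlations, specific graphlet
frequencies) are reproduced only as worked examples on printed summary
numbers or as qualitative rank properties — never re-estimated from
synthetic data.

## 6. Numerical conventions and degenerate inputs

* All indices are 1-based (the R idiom); written files carry explicit
  vertex IDs (`v1`, `v2`, ...) so 0-based external tools can map columns
  unambiguously.
* Every stochastic operation takes a `seed` and restores the caller's RNG
  state; the pipeline splits one master seed per stage, so a single
  integer reproduces a whole run bit-for-bit (manifests carry md5
  checksums to verify this).
* Correlations are clamped to [−1, 1] against floating-point overshoot;
  the covariance matrix is symmetrized as `(ρ + ρᵀ)/2` before use.
* Degenerate inputs fail loudly with named offenders: rank-deficient
  designs (collinear columns listed), zero-variance vertices (indices
  listed), empty parcel classes, empty decoding masks, `t = 0` thresholds,
  negative graphlet counts, p-values outside [0, 1].
* `holm_adjust` and the Bonferroni flag rule are exact implementations of
  their definitions; ties and all-equal inputs reduce to `min(1, m·p)`.

## 7. Known limitations

* The exact census is enumeration-bound: beyond the subgraph guardrail the
  sampler is the intended tool, and its per-class precision on very rare
  classes is limited by the hit rate (their standard errors say so).
* The landmark decomposition inherits the usual instability of close
  singular values; `align_components()` quantifies, but cannot remove,
  rotation between nearly tied components.
* The CIFTI/GIFTI adapters for real surface data are not included in this
  build (no reader available in the target environment); cohort and map
  adapters accept the documented TSV formats instead.
* Pržulj-order positions in the four textually unpinned groups noted in
  §4 rest on structural inference; if a machine-readable reference
  ordering is ever available, the shipped table can be asserted against it
  directly (the tests already isolate it as data).
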