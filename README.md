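# mcnet — vertex-level myelin covariance networks

`mcnet` builds and characterizes **myelin covariance networks (MCNs)**:
structural covariance networks whose edges are the Pearson correlations,
across individuals, of a cortical myelin proxy (the T1w/T2w ratio) at pairs
of surface vertices. It is aimed at network-neuroscience researchers who
want a tested, reproducible desk-scale pipeline for:

1. **Confound residualization** — per-vertex OLS of the myelin map on
   `[1, age, age², gender, age×gender]`; the residuals `R_v = M_v − M̂_v`
   feed everything downstream.
2. **Covariance network & signed strength** — the vertex × vertex Pearson
   matrix `ρ_ij = cov(R_i, R_j)/√(var R_i · var R_j)` and three per-vertex
   strength maps (sum of negative, positive, and all off-diagonal
   correlations, no thresholding), with `full = positive + negative`
   holding exactly.
3. **Principal gradients** — landmark-approximated principal components of
   the connectivity profiles (a fast approximation that never forms the
   full vertex × vertex matrix), with a full-matrix decomposition as the
   in-package oracle and per-component variance-explained fractions.
4. **Class profiles & decoding** — per-class means over a cytoarchitectonic
   parcellation with the across-class sample standard deviation, Pearson
   decoding against term-map banks on the jointly non-zero vertex mask, and
   correlations with multimodal feature maps under Bonferroni
   (`p > α/m` ⇒ not significant) or step-down Holm adjustment.
5. **Higher-order graphlet landscape** — threshold the network at signed
   cutoffs (edges `ρ ≤ t` for `t < 0`, `ρ ≥ t` for `t > 0`; default
   −0.4, −0.2, 0.2, 0.4), count the 30 connected 2–5-node induced
   subgraph classes G0–G29 in Pržulj order (exactly via compiled ESU
   enumeration, or by an unbiased edge-anchored sampler with standard
   errors), and normalize counts as
   `f*_Gi = log10(1 + (f_Gi + 1) / Σ_j (f_Gj + 1))`.

Because individual-subject neuroimaging data of this kind is
access-restricted, the package ships a first-class **synthetic cohort
generator** (`generate_cohort()`) that plants orthogonal low-rank gradient
structure, age/gender confound effects and (optionally spatially smoothed)
noise, carrying the ground truth alongside the data so recovery is testable
end to end.

## Worked example

```r
library(mcnet)

co  <- generate_cohort(cohort_spec(seed = 7))   # 200 subjects x 300 vertices
res <- residualize(co)
net <- covariance_network(res)
s   <- strength_maps(net)

lmk <- select_landmarks(300, 30, seed = 7)      # 10% landmarks
g   <- approximate_gradients(landmark_connectivity(res, lmk), k = 3,
                             landmarks = lmk)
g
#> Gradient set: k = 3 over 300 vertices
#>   variance explained: 82.31%, 13.79%, 2.57%

align_components(g, exact_gradients(net, 3))$r  # vs full-matrix oracle
#> [1] 0.9935554 0.9915152 0.9921359

gradient_strength_matrix(g, s)                  # Holm-adjusted, family of 9
#>   map  feature       r         p     p_adj significant
#> 7  G1     full  0.9266 1.34e-128 1.21e-127        TRUE
#> 8  G2     full  0.3206  1.35e-08  1.08e-07        TRUE
#> ...

normalize_census(census_sampled(threshold_graph(net, -0.2),
                                n_samples = 50000, seed = 7))
#> Normalized graphlet frequencies (displayed formula)
#>   top classes: G16=0.1062, G20=0.1035, G11=0.0797, G10=0.0654, G9=0.0268, ...
```

The three landmark gradients match the full decomposition at |r| > 0.99,
the first gradient is strongly coupled to full-network strength (here
r = 0.93 on synthetic data), and the negative-threshold network is
dominated by star-like and biclique classes (G10/G11/G16/G20) — the
higher-order signature of anticorrelated gradient poles — while positive
thresholds favor clique/path/triangle classes.

## Full pipeline and CLI

```r
cfg <- pipeline_config(cohort_spec = cohort_spec(seed = 1),
                       output_dir = "run1", seed = 1)
manifest <- run_pipeline(cfg)   # TSV/JSON outputs + md5-checksummed manifest
```

A command-line launcher with verbs `simulate`, `covnet`, `gradients`,
`profile`, `decode`, `graphlets`, `run-all` is installed at
`system.file("cli/mcn.R", package = "mcnet")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mcn.R", package="mcnet"))')" \
    run-all --out run1 --seed 1
```

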