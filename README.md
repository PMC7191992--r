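# berryshape

Image-based fruit-shape phenotyping for quantitative genetics. Given binary
segmentation masks of individual fruit (strawberry is the motivating crop)
and a genotype × harvest × block field design, `berryshape`:

1. **normalizes** each mask to a scale-free 100 × 100 binary raster;
2. **extracts a 66-feature shape dictionary** — linear/geometric
   descriptors (circularity, aspect ratios, solidity, Feret ratio, marginal
   moments), elliptical Fourier coefficients (5 harmonics) with PCA scores,
   Procrustes pseudo-landmark latent region scores (tip, neck, sides),
   eigen-image ("EigenFruit") principal components, and row/column biomass
   profile PCs;
3. **clusters** the flattened images with k-means for k = 2..10 and orders
   the discovered clusters on an ordinal scale with **PPKC** (Principal
   Progression of k Clusters);
4. **selects** informative features by permutation out-of-bag importance
   over many random forests, consolidated into nested large/medium/small
   sets;
5. **classifies** shapes with LDA and an RBF SVM under an unstratified
   split / cluster-train / project-test protocol; and
6. estimates **clone-mean broad-sense heritability** of every feature and
   of the ordinal shape classes.

A parametric berry simulator (`berry_outline()`, `simulate_population()`,
`simulate_shape_classes()`) generates populations with known genetic and
residual variance components, so the whole pipeline is testable without any
external images.

## The core method: PPKC

k-means labels are nominal; quantitative genetics wants ordinal scores. For
a focal number of clusters *k*, PPKC profiles each focal cluster *f* by its
ancestry proportions across every coarser clustering *j* = 2..*k*−1:

    M[(j,c), f] = |samples in focal cluster f ∩ level-j cluster c| / |focal cluster f|

a ((k²−k)/2 − 1) × k matrix whose columns each sum to k − 2. The
variance–covariance matrix of the columns of **M** is eigendecomposed,

    Σ_M = V Λ V⁻¹,

and clusters are ranked by their elements on the eigenvector of the largest
eigenvalue. Only the ranks are interpreted; an order and its reverse are
equivalent, and the k = 2 order is arbitrary. Clusters whose eigenvector
elements nearly coincide are flagged — the symptom of overfitted, duplicated
clusters.

Heritability on a clone-mean basis uses

    H² = σ²_G / (σ²_G + σ²_E / (h·r)),

with σ²_G, σ²_E from a REML linear mixed model (genotype random; harvest
and block fixed) for quantitative features, or from a cumulative-logit
mixed model (latent residual π²/3) for ordinal classes; *h* and *r* are the
harmonic means of harvests per genotype and replicate plots per harvest.

## Worked example

```r
library(berryshape)

# simulate a replicated population along the prolate -> oblate gradient
design <- population_design(n_genotypes = 25, n_harvests = 2, n_blocks = 2,
                            sigma2_G = 0.15, sigma2_E = 0.01, seed = 7)
sim <- simulate_population(design)

# cluster the flattened images and order the clusters
px <- pixel_matrix(sim$images)
hist <- cluster_history(px, k_range = 2:6, n_restarts = 5, seed = 3)
pk <- ppkc(hist)
cor(pk$ordinal_assignments$k4, sim$truth$e, method = "spearman")
#> [1] 0.9627101         # ordinal class tracks true elongation (the sign
#>                       # is arbitrary: an order and its reverse are
#>                       # equivalent)

# the feature dictionary (first fruit is a strongly prolate berry)
fx <- extract_features(sim$images[1:30])
round(fx$features[1, c("SI", "Circ", "AR", "Round", "Solid")], 3)
#>           SI  Circ    AR Round Solid
#> s00001 2.632 0.727 2.598 0.385 0.998

# clone-mean heritability of the true latent trait
vc <- fit_quantitative(sim$truth$e, sim$records)
ds <- design_summary(sim$records)
h2_clone_mean(vc$sigma2_G, vc$sigma2_E, ds$h, ds$r)
#> [1] 0.9914994         # high: genetic variance dominates plot residual
```

`run_pipeline(run_config(...))` chains every stage and writes CSV outputs
plus a JSON manifest; `inst/cli/berryshape.R` is a thin Rscript wrapper
with `simulate`, `features`, `cluster`, `h2`, and `run` subcommands.

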