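---
title: "Shape phenotyping with berryshape: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape phenotyping with berryshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(berryshape)
```

# The problem

Fruit shape in clonally propagated crops such as garden strawberry is a
multi-dimensional, continuously varying trait that breeders have
traditionally scored by eye on ad hoc categorical scales. `berryshape`
implements a complete image-based alternative: binary segmentation masks of
individual fruit are normalized to a common raster, a dictionary of
quantitative shape features is extracted, shapes are grouped by unsupervised
clustering, the discovered groups are placed on an ordinal scale by the
Principal Progression of k Clusters (PPKC) algorithm, informative features
are selected by random-forest out-of-bag importance, shapes are classified
with LDA and SVM under a cross-validation protocol, and clone-mean
broad-sense heritability is estimated for every derived phenotype.

# Image normalization

Masks are binary matrices with fruit = 1. `extract_objects()` splits a
segmented image into per-fruit masks by 4-connected component labeling,
cropping each to its bounding rectangle. Components below 50 px^2 are
dropped as segmentation specks — real pipelines flag and hand-fix failed
segmentations; an automated guard replaces that manual step. Holes are left
unfilled: nothing in the processing convention calls for filling them, and
they are rare in practice.

`normalize_mask()` pads to a square of side max(H, W), rescales so the
larger dimension is 1,000 px, then downsamples to 100 x 100 and
re-binarizes at 0.5 (ties count as foreground). Both resampling steps are
exact area averages (a separable box filter), which is deterministic and
resolution-robust; the interpolation used by the original imaging toolchain
is unspecified, so pixel-exact agreement with archival rasters is not
guaranteed. For synthetic rasters, which never exist in an archival
1,000-px form, `scale_px = NULL` collapses the two box filters into their
exact composition and skips the intermediate re-binarization.

`flatten_image()` unrolls the 100 x 100 grid row-major (origin top-left, y
downward) into the 10,000-element vector used by clustering and the
eigen-image analysis; the fixed convention keeps PCA loadings reproducible.

# The feature dictionary

Sixty-six named features per fruit:

* **11 linear/geometric descriptors** — SI (bounding height/width), Circ
  = 4&pi;A/P^2, BAR (width/height), AR (best-fit-ellipse major/minor, from
  second-order pixel moments), Round = 4A/(&pi; major^2), Solid (area /
  convex hull area), FAR (max/min Feret via rotating calipers), HW (height
  of the widest row above the base, in units of total height; ties across
  a flat maximum are averaged), and Var/Skew/Kurt of the marginal
  foreground distribution along the horizontal axis (Kurt is excess
  kurtosis). These are computed per fruit and never re-fit.
* **20 elliptical Fourier coefficients** (5 harmonics, Kuhl–Giardina,
  chord-length parametrization), summarized by 20 PCA scores. No
  first-harmonic normalization by default — the rasters are already scale-
  and orientation-normalized — but `normalize = TRUE` enables it. Under
  arc-length parametrization only a circle is a pure first harmonic; an
  ellipse retains a small known remainder in higher harmonics, which is why
  exactness tests use the circle.
* **5 latent region scores** from 50 equal-arc-length pseudo-landmarks:
  after full generalized Procrustes alignment (translate, unit centroid
  size, iterative rotation to the mean, tolerance 1e-8), each landmark gets
  an independent 2-D PCA; region scores (Tip, Neck, SideLeft, SideRight)
  are the unit-variance first principal components of fixed landmark
  groups, and Shape is the first principal component of the four region
  scores. This region-PCA construction replaces a confirmatory
  factor/SEM estimator: it targets the same latent constructs with an
  ordinary spectral method, avoids a bespoke SEM dependency, and the region
  features are not among the features selected downstream, so results are
  insensitive to the difference. The Procrustes mean is defined only up to
  rotation; it is canonicalized by pointing landmark 1 (tip-adjacent)
  straight up, which also makes alignment invariant to sample order.
* **20 eigen-image scores** ("EigenFruit"): PCA of the flattened binary
  vectors. Loading signs are fixed by making each loading's
  largest-magnitude element positive.
* **10 biomass-profile scores**: 5 PCs each of the 100 row sums
  (horizontal) and 100 column sums (vertical).

The headline dictionary size of record is 68; the enumerable registry above
yields 66 columns. The identity of the remaining two features is not
recoverable from the written description, so the registry documents the
discrepancy (version 1.0) rather than inventing columns.

# Clustering and PPKC

`kmeans_images()` runs Lloyd's algorithm with Euclidean distance, best of
25 restarts (default), 300 iterations, with empty-cluster repair by
reseeding from the farthest point. `selection_criteria()` reports WSS,
adjusted R^2 = 1 − (WSS/(n−k))/(TSS/(n−1)), and AIC/BIC from a
spherical-Gaussian surrogate (pooled variance WSS/(nd), p = kd + 1
parameters). A caveat discovered while validating at desk scale: the
surrogate's fit term scales with n·d while its penalty scales with
d·log(n), so for n in the hundreds and d = 10,000 the BIC keeps improving
as long as any split removes more than ~2·log(n)/n of the WSS — which
k-means splits essentially always do when within-class variability is
driven by a continuous latent such as elongation. The surrogate is
therefore useful for comparing nearby k but its global argmin need not
stabilize at the generative class count on small populations.

PPKC orders the nominal clusters. For focal k, the matrix M profiles every
focal cluster by the proportions of its members in each cluster of every
smaller k ((k^2−k)/2 − 1 rows; every column sums to k − 2 exactly). The
covariance between the columns of M (sample covariance, divisor rows − 1 —
the scalar does not affect ranks) is eigendecomposed and clusters are
ranked by their elements on the leading eigenvector. Only ranks are
interpreted, an order and its reverse are equivalent, and k = 2 is declared
arbitrary. Ties in eigenvector elements are broken by cluster size then
label. Orientation is chained for stable output: at k &ge; 4 the sign that
correlates positively with the order inherited from k − 1 (through majority
cluster ancestry) is chosen; at k = 3 the cluster with the largest mean
height/width ratio goes first when an orientation statistic is supplied.

Degenerate case worth knowing: when two focal clusters have *identical*
ancestry profiles (e.g., exactly discrete classes whose lower-k clusterings
cut exactly at class boundaries), their eigenvector elements tie exactly
and no assignment-based ordering can separate them. The convergence
diagnostic (`min_gap`, flagged below `gap_tol`, default 0.01 of the
eigenvector range) reports this; it is also the overfitting symptom in
which new clusters duplicate old ones. There is no field-sanctioned default
for the threshold, so it is exposed as a knob.

# Feature selection and classification

`rf_importance()` averages permutation out-of-bag importance over many
forests (defaults 100 forests x 2,000 trees; tests scale these down). The
two-stage selection follows the interpretation/prediction contract of
variable-selection-by-forests: the interpretation set keeps features whose
mean importance beats the largest importance earned by shuffled-copy noise
probes (a deterministic, explainable replacement for a CART-threshold
heuristic); the prediction set adds features greedily in importance order
while out-of-bag error keeps dropping by more than its replicate standard
deviation. `select_across_k()` consolidates across k: the large set needs
membership in &ge; 3 prediction sets; the medium and small sets further
require the feature's mean importance to beat the median and mean of all
observed importances. Thresholds are always recomputed from the data at
hand, and the three sets are nested by construction.

Classification follows the split/cluster/project protocol: unstratified
random splits (80/20, 50/50, 20/80), k-means on the training pixels only,
nearest-centroid assignment of test images, PPKC on the training history,
PCA feature models re-fit on the training rows with test rows projected
through the training means and loadings (per-fruit geometric descriptors
are simply copied), then LDA (pooled covariance; ridge 1e-6 on singularity)
and an RBF SVM with cost 1 and gamma = 1/#features — the reference
implementation defaults. The historical name "SVR" in this protocol refers
to what is operationally soft-margin SVM classification of a factor
response, and it is reported here as SVM. Metrics are accuracy and
macro-averaged one-vs-rest precision, recall, and false-positive rate over
10 fresh iterations (clustering re-run per iteration, since training-set
images are clustered per experiment).

# Heritability

Clone-mean broad-sense heritability is H^2 = &sigma;^2_G / (&sigma;^2_G +
&sigma;^2_E / (h·r)), with h the harmonic mean of observed harvests per
genotype and r the harmonic mean of replicate plots per harvest, both
recomputed from the metadata. Quantitative features use a REML linear mixed
model (genotype random; harvest and block fixed — with only 2 harvests and
3 blocks observed, fixed effects are the appropriate treatment), after
averaging fruit-level subsamples to plot means (the model has no subsample
term). Ordinal shape classes use a cumulative-logit mixed model with a
genotype random intercept, fitted by maximum likelihood with 15-node
Gauss–Hermite quadrature; the latent residual is fixed at &pi;^2/3, the
logistic threshold-model convention, and that convention is recorded in the
output metadata so values are comparable across runs. (Whether the residual
should instead be the estimated plot variance is genuinely open; the
&pi;^2/3 convention is the default and the metadata records which was
used.) With fewer than 3 samples in a category or a failed optimization the
fit falls back, flagged, to a Gaussian REML fit on the integer scores.

# The synthetic generator

`berry_outline()` draws r(&theta;) = 1 + a1·cos&theta; + a2·cos2&theta;
scaled vertically by elongation e — the smallest shape family exhibiting
tip, neck, and elongation variation, mapping onto the observed tall/thin to
short/wide gradient. `simulate_population()` replicates the field design:
per genotype a genetic effect ~N(0, &sigma;^2_G), per plot a residual
~N(0, &sigma;^2_E), plus fixed harvest/block offsets, with elongation
clipped to [0.4, 2.5] (flagged; the unclipped latent is also recorded so
variance-component checks can target the generative model exactly). Default
gradient c(0.7, 1.8) with &sigma;^2_G = 0.1 spreads a population across
visibly prolate to oblate forms. `simulate_shape_classes()` instead places
classes at fixed elongations 0.55 / 0.95 / 1.45 / 2.1 with within-class SD
0.04 — separations roughly ten times the within-class spread, i.e., wide —
for cluster-recovery and classification studies.

What the generator does *not* emulate: achene and calyx texture,
segmentation artifacts, lighting, camera perspective, or correlated
non-genetic structure (e.g., spatial field trends). Passing tests therefore
demonstrate correctness of the algorithms under a known generative model,
not performance on field images.

# Problem sizes and numerical choices

Test and validation runs use populations of 100–500 rendered berries
(rasterized at 160 px, normalized to 100 x 100), k-means with 2–10
restarts, forests scaled to 3–5 x 200–300 trees, and mixed-model
simulations with 150–500 genotypes; these sizes give stable estimates of
every property asserted while keeping runs reproducible on a single CPU.
Key numerical conventions: marching-squares contours are smoothed with an
adaptive (1,2,1)/4 filter (about one pass per 60 contour points, at most
30) to remove the staircase bias that would otherwise inflate perimeters by
~5%; rasterization centers the polygon in the pixel grid so mirror
symmetry survives discretization; PCA keeps the full eigenvalue spectrum so
variance conservation is exact; all randomness flows from explicit integer
seeds with one stream per operation.
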