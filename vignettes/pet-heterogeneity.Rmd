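---
title: "Heterogeneity analysis of FDG PET tumour volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity analysis of FDG PET tumour volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In neurofibromatosis-1 (NF1), symptomatic benign neurofibromas and
malignant peripheral nerve sheath tumours (MPNSTs) can be difficult to
distinguish non-invasively. On ^18F-FDG PET, malignant transformation
shows up in two ways: higher tracer uptake (captured by SUV metrics) and
more *spatially heterogeneous* uptake (captured by texture metrics).
`petrad` implements the full analysis chain for this discrimination task:
per-lesion texture quantification from a segmented volume of interest
(VOI), and the cohort-level statistics that compare benign and malignant
groups at two acquisition timepoints.

The package assumes masks are already on the PET voxel grid. Clinically,
low-uptake lesions are often contoured on the co-registered CT; how such
contours are resampled onto the PET grid (nearest-neighbour versus
fractional-overlap rules) is a protocol decision we deliberately leave
upstream, since no single convention is standard.

# Feature definitions and conventions

## Quantisation

Voxel intensities inside the VOI are mapped to `Ng = 64` discrete grey
levels by fixed-bin-number min–max binning over the VOI's own range:

$$\ell(v) = \min\!\left(N_g,\ 1 + \left\lfloor N_g \frac{v - v_{\min}}{v_{\max} - v_{\min}} \right\rfloor\right)$$

The top edge is closed (`v_max` maps to `Ng`); a constant VOI maps to
level 1. Because the bin edges come from the VOI itself, every quantised
texture feature is invariant under strictly increasing affine rescaling
of the intensities — a property the test suite checks directly, and the
reason absolute-scale information enters only through the SUV metrics.

## First-order features

SUVmax, SUVmean and the population SD are computed on the raw SUV values
(we use the population rather than the sample SD; at VOI sizes of
hundreds of voxels the difference is negligible, but a fixed convention
is needed for exact tests). Entropy $-\sum_l h_l \log_2 h_l$ and
uniformity $\sum_l h_l^2$ are computed on the quantised histogram
$h_l$. Entropies throughout the package are in bits (log base 2); a
64-level histogram therefore has entropy at most 6 bits.

SUVpeak is the maximum over VOI voxels of the mean SUV in a 1.0 ml
sphere (radius 6.2 mm) centred on that voxel. Sphere membership is
decided by voxel-centre distance in physical millimetres, so the sphere
is anisotropic in index space; sphere voxels outside the image are
excluded from the mean, while voxels outside the VOI but inside the
image contribute (only the centre is constrained to the lesion, the
usual convention). The sphere volume is configurable
(`peak_volume_ml`).

## GLCM (second-order) features

The grey-level co-occurrence matrix is built in 3D over the 13 unique
direction offsets at Chebyshev distance 1, counting only pairs with both
voxels inside the VOI, each pair in both orders (symmetric matrix), all
directions merged into a single matrix before normalisation. Whether a
clinical implementation merges or averages per-direction matrices is
rarely reported; merged counting is the most reproducible choice and the
one implemented here. Features: contrast $\sum (i-j)^2 p_{ij}$, entropy
$-\sum p_{ij}\log_2 p_{ij}$, uniformity (angular second moment)
$\sum p_{ij}^2$, and homogeneity as the inverse difference moment
$\sum p_{ij}/(1+(i-j)^2)$ (several "homogeneity" variants exist in the
literature; the inverse difference moment is the classical one). A VOI
with no adjacent voxel pair has no GLCM; its features are reported
missing, never zero.

## NGTDM (high-order) features

The neighbourhood grey-tone difference matrix follows the original
Amadasun–King construction extended to 3D: the neighbourhood is the
26-connected shell (adjacent voxels in the same and adjacent planes,
distance 1 in index space regardless of anisotropic spacing), and only
voxels whose complete neighbourhood lies inside the VOI contribute.
With $s_i$ the summed absolute deviation of level-$i$ voxels from their
neighbourhood mean, $p_i$ the level occupancies, $N$ the contributing
voxels and $G$ the number of occupied levels:

- coarseness $= 1/(\varepsilon + \sum_i p_i s_i)$, with
  $\varepsilon = 10^{-6}$ capping the value at $10^6$ for perfectly
  flat textures (configurable, `ngtdm_epsilon`);
- contrast $= \bigl[\frac{1}{G(G-1)}\sum_i\sum_j p_i p_j (i-j)^2\bigr]
  \cdot \bigl[\frac{1}{N}\sum_i s_i\bigr]$, defined as 0 when $G = 1$;
- busyness $= (\sum_i p_i s_i) / \sum_i\sum_j |i\,p_i - j\,p_j|$ over
  occupied levels, missing when the denominator vanishes;
- complexity $= \frac{1}{N}\sum_i\sum_j \frac{|i-j|}{p_i+p_j}
  (p_i s_i + p_j s_j)$ over occupied levels.

A VOI thinner than three voxels along any axis has no complete
neighbourhood; its four NGTDM features (and the combined
SUVmax/NGTDM-contrast ratio) are missing. Missing features propagate —
they are excluded pairwise from every downstream statistic and never
imputed. Note that published clinical coarseness values for PET VOIs
often sit orders of magnitude away from the canonical Amadasun–King
scale, suggesting in-house normalisations; `petrad` implements the
canonical formulas and makes no attempt to match any particular
software's scaling.

All texture and SUVpeak computations are validated against independent
brute-force loop implementations (explicit per-voxel neighbour loops and
sphere enumeration) in the test suite, to $10^{-10}$ on random VOIs.

# Statistical analysis

The cohort layer is unconditionally nonparametric, matching practice for
small skewed PET cohorts:

- **Group comparison**: two-sided Mann–Whitney U with midrank ties.
  The p value is exact (full enumeration) when the pooled sample size is
  ≤ 12 with no ties, and otherwise uses the normal approximation with
  tie-corrected variance and continuity correction.
- **AUROC**: the empirical (tie-aware) area, identical to
  $U/(n_1 n_2)$; variance, 95% Wald CI and paired comparisons against
  SUVmax via DeLong's structural-components estimator. With
  `direction = "auto"` a feature lower in malignant lesions is flipped so
  the reported AUROC is ≥ 0.5 and the direction is recorded. The test
  suite cross-checks the whole DeLong machinery against `pROC` and a
  stratified bootstrap.
- **Diagnostic metrics**: the cutoff maximises the Youden index over all
  midpoints between adjacent distinct scores, with ties broken toward
  higher specificity (then toward the higher cutoff); sensitivity,
  specificity, PPV, NPV and accuracy are reported at that cutoff. These
  metrics are invariant under monotone transforms of the score.
- **Inter-observer agreement**: two-way random-effects,
  absolute-agreement, single-measures ICC(2,1), with the F-based 95% CI;
  a consistency form is available (`form = "consistency"`). Identical
  raters give exactly 1.
- **Dual-timepoint change**: per patient and feature,
  $100\,(x_{4h} - x_{1.5h})/x_{1.5h}$, missing when the early value is 0.
  Reports show the pooled median (range) with a Mann–Whitney comparison
  of the two classes, and the AUROC of the change itself. Published
  percentage-change tables are often ambiguous about sign and
  denominator; this fixed convention is a documented package choice.

Tests are two-sided at α = 0.05 with no multiple-testing correction
(the design mirrors a single exploratory clinical analysis; users
comparing many features confirmatorily should adjust externally).
Every report row carries the method configuration, and reports are
written as rounded CSVs (4 significant figures by default) plus a
full-precision JSON mirror; reruns are byte-identical.

# The phantom generator

Because clinical PET data cannot ship with the package, validation runs
on a seeded two-class phantom cohort (`phantom_spec()`, `make_cohort()`).
Defaults encode the cohort structure the analysis targets: 30 benign and
24 malignant lesions; benign mean SUV 2.3 versus malignant 7.0; total
voxelwise SD ≈ 0.27 versus ≈ 1.32 (texture SD 0.1 / 1.3 plus measurement
noise SD 0.25); benign −15% washout versus malignant +10% retention
between timepoints; voxels 4.7 × 4.7 × 3.27 mm; ellipsoidal lesions with
semi-axes 14–26 mm (volumes bracketing typical benign ≈ 23 ml and
malignant ≈ 60 ml lesions); background SUV 0.5. Each case gets an
independent RNG substream derived from the root seed, so cohorts are
reproducible file-for-file and cases are independent.

## Texture model

Lesion heterogeneity is a standardised spatial field scaled by the class
heterogeneity SD — the single per-class texture knob. The field mixes
two components (`rim_gradient_weight`, default 0.85):

1. a **centre-to-rim radial gradient**: the normalised ellipsoidal
   radius raised to a random exponent (U(2.2, 3.8)) around a randomly
   offset core — the necrotic-core / hypermetabolic-rim pattern of
   aggressive lesions. Geometrically, this component spreads lesion
   voxel values broadly across their range (for exponent 3 the value
   histogram over the ellipsoid volume is exactly uniform);
2. a **correlated Gaussian field**: white noise smoothed with a
   Gaussian of σ = 6 mm (about the PET point-spread width, i.e. the
   smallest structure PET can represent), renormalised.

Independent voxelwise Gaussian noise (SD 0.25 SUV, typical of
clinical-count FDG images) is added everywhere, and values are clipped
at 0 (a slight truncation of the noise distribution, noted rather than
corrected). The late volume scales the noise-free signal by the class
retention slope and adds fresh noise.

Why the radial component? Min–max quantisation is affine-invariant, so
first-order entropy and uniformity see only the *shape* of the VOI
histogram relative to its own range. A purely Gaussian random field —
whatever its SD — produces nearly the same histogram shape in both
classes, and during design we measured that it cannot reproduce the
clinically observed entropy/uniformity contrast between classes
(separation plateaus well below the SUV-based features regardless of
correlation length). The rim gradient gives malignant lesions what real
ones have: organised structure spanning the uptake range, hence a broad
histogram (higher entropy, lower uniformity), while benign texture — at
SD 0.1, well below the noise floor — remains effectively iid noise with
a tight unimodal histogram. The class contrast still enters through the
heterogeneity SD alone; the field construction is shared.

## What the phantom does and does not emulate

The phantom reproduces the *qualitative* cohort structure: malignant
lesions higher on all SUV metrics and SD, higher first-order entropy,
lower uniformity, directionally consistent retention differences, and
no parameter beating SUVmax in paired DeLong comparisons. It does
**not** emulate: between-patient variability of class mean uptake (all
benign lesions share one mean, so phantom AUROCs for SUV metrics sit at
or near 1.0, above clinically plausible values); scanner physics
(point-spread blur at lesion boundaries, Poisson sinogram noise,
reconstruction artefacts, motion); irregular lesion shapes; or the
absolute magnitudes of clinical texture features (clinical first-order
entropies of symptomatic neurofibroma VOIs are far below the phantom's,
reflecting generous CT-drawn contours dominated by low-uptake tissue).
Passing the phantom-based tests therefore demonstrates that the pipeline
*measures and ranks* heterogeneity correctly under a controlled model,
not that clinical effect sizes will match.

# Validation design and problem sizes

The test suite pairs every non-trivial computation with an independent
oracle: brute-force loop implementations for GLCM/NGTDM (102 random VOIs
up to 8×8×8 at Ng ∈ {4, 8, 64}), exhaustive pair counting for the AUROC,
`pROC` for the DeLong variance and paired test, a 2000-replicate
stratified bootstrap for the variance of an AUROC difference, and
closed-form degenerate cases (flat VOIs, separated samples, identical
raters). Frequentist calibration is checked by simulation at the
cohort's size (30/24): the Mann–Whitney type-I error over 2000 null
cohorts and DeLong CI coverage over 500 cohorts with true AUROC 0.8.
These sizes keep the default suite fast while leaving Monte-Carlo error
well inside the asserted bands. `scripts/acceptance.R` re-runs the
pipeline and calibration end-to-end from a single seed and writes all
headline numbers to JSON.

# Known limitations

- Masks must already live on the PET grid; no resampling is provided.
- GLCM aggregation (merged vs per-direction averaging), homogeneity
  variant, and the NGTDM ε are conventions, configurable but defaulted;
  results are only comparable across software when these match.
- The DeLong CI is Wald-type and can touch the [0, 1] boundary for
  near-separable data; boundary-respecting intervals (e.g. logit) are
  not implemented.
- `suv_peak` assumes the 1 ml sphere is meaningful at the given voxel
  size; at very coarse grids the sphere contains few voxels.
- The phantom's limitations listed above mean clinical effect sizes and
  texture magnitudes should never be read off phantom runs.
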