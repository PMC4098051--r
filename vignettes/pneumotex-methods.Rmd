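---
title: "Power-spectrum texture classification of pneumoconiosis ROIs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-spectrum texture classification of pneumoconiosis ROIs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumotex)
```

## The problem

Pneumoconiosis presents on chest radiographs as diffuse small opacities —
rounded (ILO size classes p, q, r) or irregular (s, t) — whose areal
concentration ("profusion", subcategories 0/0 through 3/3) grades disease
severity.  Early, low-profusion disease is hard to read: the texture change
is subtle and is confounded by normal anatomy (vessels, ribs, the smooth
intensity gradient from lung centre to chest wall).

`pneumotex` implements a computer-aided detection scheme that classifies
small (32 × 32 pixel, 0.175 mm/pixel) regions of interest as normal or
abnormal from the distribution of their texture energy over spatial
frequency, using a hybrid of threshold rules and small neural networks
over three complementary image-enhancement branches.

## The classification scheme

Every ROI passes through the following stages.

**Trend correction.**  A second-order polynomial surface
$f(x,y) = c_{00} + c_{10}x + c_{01}y + c_{20}x^2 + c_{11}xy + c_{02}y^2$
is fitted to the ROI by least squares over centred pixel coordinates and
subtracted.  This removes the gross-anatomy intensity gradient while
leaving the texture.  The fit is a linear projection (applying it twice
changes nothing) and the residual has zero mean by construction.

**Enhancement branches.**  Three independent transforms of the
trend-corrected ROI feed the feature extractor:

1. *Radial window* — each pixel is weighted by a Hanning, Hamming or
   Blackman taper evaluated at its radius $n=\sqrt{x^2+y^2}$ from the ROI
   centre ($H(n)=0.5+0.5\cos\frac{2\pi n}{N-1}$, and analogously for the
   other two).  This suppresses the spectral leakage that the ROI edge
   discontinuity smears along the $u$ and $v$ frequency axes.  Radii
   beyond $(N-1)/2$ (the ROI corners) are clamped to the edge value, which
   avoids cosine wrap-around; the window is applied in the spatial domain,
   the standard leakage-reduction practice.
2. *Top-hat transform* — the image minus its grayscale opening with a flat
   square structuring element (13–25 px; the package default is 21 px).
   Bright structures smaller than the element (the opacities) survive;
   wider structures (large vessels) are reconstructed by the opening and
   cancel.  Borders are handled by edge replication, and the output is
   nonnegative by the anti-extensivity of opening.
3. *GLCOM feature image* — the ROI is min–max quantised to 6 bits and the
   joint probability of gray-level pairs at displacement $d$ (1–3 px)
   along 45°/225° is accumulated into a symmetric 64 × 64 matrix.  The
   probability matrix itself is the "feature image": its own Fourier
   spectrum summarises how concentrated or dispersed the co-occurrence
   structure is.

**Spectral features.**  For each branch image the centred 2-D power
spectrum $|F(u,v)|^2$ is computed.  Candidate radial lines through the
spectrum centre are the quantised directions to every lattice point on the
half-spectrum boundary; each line is scored by the sum of spectrum values
at integer radii $1 \dots N/2$ (nearest-lattice sampling, DC excluded;
ties go to the smaller angle).  The best and second-best directions are
the *main* and *second axes*.  Their two profiles, divided by the maximum
over the concatenated pair, form the branch feature vector: 32 values for
the window and top-hat branches (16 + 16), 64 for the GLCOM branch
(32 + 32), 128 for the combined vector (window ‖ top-hat ‖ GLCOM).
Features are dimensionless, lie in $[0,1]$, and are invariant to the
overall image amplitude.

**Rule-based stage.**  DFT bins 1 and 2 of a 32-px ROI at 0.175 mm/pixel
correspond to 0.179 and 0.357 cycles/mm — the spatial frequencies of
nodular patterns.  From the training set only, the rule records, per
branch, the *maximum* feature value among normals and the *minimum* among
abnormals at those two bins.  A test ROI exceeding the normal maximum at
either bin is "obviously abnormal"; one below the abnormal minimum at both
bins is "obviously normal"; anything else is undecided.  By construction
no training ROI is ever obviously mislabelled.  With three branches the
votes combine by logical OR, with abnormal taking precedence over normal
on conflict (minimising false negatives, the usual CAD convention).

**ANN stage.**  Undecided ROIs are scored by a three-layer perceptron —
32-17-1 for single image branches, 64-33-1 for GLCOM, 128-65-1 for the
combined vector (hidden size $d/2+1$ throughout) — with logistic sigmoid
units, trained to targets 0.1 (normal) and 0.9 (abnormal) by per-pattern
backpropagation with momentum.  Rule-forced decisions map to scores 1.0
and 0.0 so ROC ranking places them beyond every network output.

**Evaluation.**  The dataset is stratified-halved into training and test
sets ten times (odd class counts split $\lceil n/2\rceil$ /
$\lfloor n/2\rfloor$).  All methods share each split's halves — the paired
design that licenses the paired $t$ test.  Per method we report the AUC
mean ± SD across splits and the vertically averaged ROC curve (mean TPR on
a fixed FPR grid, 0 to 1 in steps of 0.01); method pairs are compared by
the two-tailed paired $t$ test on per-split AUCs.  The AUC is the
trapezoidal area under the empirical ROC, identical to the Mann–Whitney
statistic with half-credit ties.

## The synthetic ROI generator

The original ILO standard radiographs are not distributable, so the
package ships a generator whose output has the statistical structure the
scheme assumes.  Each ROI is composed of:

* a second-order polynomial background (default level 2048 on the nominal
  12-bit scale) standing in for the gross-anatomy gradient;
* correlated Gaussian noise — white noise circularly convolved with a
  unit-energy Gaussian kernel (correlation length 0.8 px), so the field
  keeps exactly the requested marginal SD (default 30) — emulating
  fine parenchymal mottle;
* vessel-like ridges: bands with Gaussian cross-profile, cross-section
  σ of 6–10 px (FWHM roughly 2.5–4 mm) and amplitude 40, the wide soft
  structures the top-hat stage exists to remove;
* for abnormal ROIs, a Poisson-distributed number of opacities: isotropic
  Gaussian blobs with FWHM drawn from the ILO class diameter range
  (p ≤ 1.5 mm, q 1.5–3 mm, r 3–10 mm) or, for the irregular classes s/t,
  random-walk line elements 3–10 px long and 1–2 px wide, with peak
  amplitude 1.5 × the noise SD.

Poisson means default to 6 / 12 / 24 per ROI for subcategories 1/1, 2/2
and 3/3.  Profusion grades areal concentration, so counts per
5.6 mm ROI are sizeable for small size classes and double per grade step;
the ordering, not the absolute level, is what downstream tests rely on.
The default study mix (`gen_study_dataset()`) uses classes p and s, the
small patterns whose spatial frequencies sit above the vessel band.  Every
ROI draws from its own RNG stream derived from the master seed and ROI
index, so datasets are reproducible and order-independent.

What the generator does *not* emulate: radiographic physics (scatter, heel
effect), ribs and pleural shadows, inter-patient anatomy variation, or the
film-digitisation chain.  Passing tests therefore demonstrate the internal
consistency and the direction of effect of the scheme on textures with the
assumed structure — not clinical performance on real radiographs.

## Numerical choices and parameter defaults

| Parameter | Default | Why |
|---|---|---|
| window kind | hanning | moderate taper; Blackman's dynamic-range loss is costly on a 32-px aperture |
| top-hat element | 21 px | mid-range of the conventional 13–25 px; presets per subcategory: 17 (1/1), 21 (2/2), none (3/3) |
| GLCOM displacement | 2 px | mid-range of 1–3; presets 1/2/3 px per subcategory 1/1–3/3 |
| GLCOM depth | 6 bit | coarse quantisation concentrates the co-occurrence mass without degrading lung-texture description |
| ANN learning rate / momentum | 0.05 / 0.9 | classic per-pattern backpropagation settings |
| ANN epochs | 100 | chosen on synthetic validation splits: 300+ passes overfit the 128-input net at ~100 training ROIs, full-batch variants undertrain |
| weight init | uniform(−0.5, 0.5), seeded | deterministic retraining |

Other fixed decisions: pixel coordinates are centred before the surface
fit (conditions the design matrix); quantisation is anchored at the
per-ROI min–max (trend-corrected values are signed); the GLCOM feature
image is normalised to unit mass (a joint probability) and carries no
physical pixel spacing, so its profile bins are indexed rather than
frequency-mapped; the second spectral axis only needs a different
quantised angle from the main one (no minimum angular separation);
all-zero spectra fall back to axes at 0° and 90° with zero profiles; an
all-zero profile is returned unnormalised with a warning flag.
Rule thresholds are learned from the normalised features of the main-axis
profile, keeping the rule and ANN stages on one feature scale.

## Problem sizes

The shipped experiments use 100 ROIs per class, ten stratified halvings,
and ten master seeds for the cross-seed directional comparison; unit tests
use 8–32 px toy images and datasets of 10–100 ROIs.  At these sizes a full
end-to-end experiment takes on the order of ten seconds per master seed.

## Known limitations

* Axis finding quantises directions to boundary lattice points and samples
  nearest lattice bins; two neighbouring directions can therefore share
  low-frequency bins, and for spectra dominated by a single very low
  frequency the second axis may be an immediate neighbour of the main one.
* The rule stage inherits the normalisation: when bin 1 is the profile
  maximum its normalised value is exactly 1 for many ROIs, so the
  "obviously abnormal" rule effectively operates on bin 2 for those ROIs.
* AUC differences between methods on synthetic data are a few points with
  split SDs of similar size; the cross-seed comparison is directional, not
  an effect-size estimate.
* The generator's opacity amplitudes and densities are calibrated to
  preserve profusion ordering and class separability, not to reproduce any
  absolute AUC level from real radiographs.
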