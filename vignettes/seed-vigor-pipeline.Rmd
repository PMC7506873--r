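---
title: "Predicting seed vigor traits from hyperspectral images: methods and design"
author: "vigorspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting seed vigor traits from hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Seed vigor — the capacity of a seed to germinate and put out a strong
seedling — is conventionally measured destructively: germinate the seed and,
days later, measure the root length and the whole seedling length.
Visible/near-infrared hyperspectral imaging offers a nondestructive proxy: a
camera records a reflectance spectrum for every pixel of every seed, and the
per-seed mean spectrum carries compositional information (starch, sugars,
moisture, pigment) that correlates with subsequent germination performance.

`vigorspec` implements the full chemometric pipeline from raw hypercube to a
model-comparison grid:

1. **Reflectance calibration.** Raw counts are converted to relative
   reflectance with white-plate and dark-current references,
   \(I = (I_{raw} - I_{dark}) / (I_{white} - I_{dark})\), per pixel and band.
2. **ROI extraction.** Each seed's spectrum is the mean reflectance over the
   pixels whose centers fall inside an ellipse drawn on the seed.
3. **Windowing.** The noisy edges of the instrument range are dropped; the
   default keeps the closed interval 430.1–971.5 nm of a 256-band
   386.7–1016.7 nm grid.
4. **Kennard–Stone splitting.** A deterministic max–min-distance design
   picks a representative training set (default 73 of 89 seeds) in full
   band space, before any selection; the remainder is the test set.
5. **Wavelength selection** on the training partition only: correlation
   ranking (HCC, top-100 by |Pearson|), the successive projections
   algorithm (SPA), and a genetic algorithm (GA), plus a no-selection
   reference.
6. **Regression**: principal component regression (PCR), partial least
   squares (PLS1/NIPALS), and kernel PCR with the Gaussian kernel
   \(k(x, y) = \exp(-\lVert x - y\rVert^2 / \sigma)\), \(\sigma = 50\)
   (note the bandwidth divides the squared distance directly).
7. **Evaluation**: Pearson correlation (CC) and RMSE between actual and
   predicted trait values on the held-out seeds, for every
   (selection × model × trait) cell.

## Models and assumptions

All three regressors center the spectra and the trait by training means; no
other preprocessing (SNV, MSC, derivatives) is applied by default, because
the pipeline's reference procedure applies none.

**PCR** regresses the centered trait on the leading principal-component
scores of the centered spectra. **PLS** extracts latent variables that
maximize covariance with the trait (univariate NIPALS; unit-norm weight
vectors; X and y deflation). Both produce coefficients in band space, and at
full rank both reproduce ordinary least squares — an equivalence the test
suite asserts against `lm()` at 1e-8.

**KPCR** performs the same score regression in the feature space of the
Gaussian kernel. The training kernel matrix is double-centered,
eigendecomposed, and the centered trait is regressed on the top-q kernel
principal scores; prediction uses the centered cross-kernel against the
stored training spectra. With the kernel replaced by the plain inner
product, KPCR collapses to PCR (asserted at 1e-6); with the Gaussian kernel
it can additionally fit smooth nonlinear functions of the dominant spectral
directions.

The number of components q is not prescribed by the reference procedure, so
all three models choose it by leave-one-out cross-validation on the training
partition, scanning 1..20 (ties to the smaller q). All three models have
orthogonal score structures, so one decomposition per LOO fold yields
held-out predictions for every q at once; at the n ≈ 100 scale of single-tray
seed studies this is cheap. The KPCR scan holds the fold's eigenbasis fixed
while scoring component counts, the standard kernel-CV shortcut.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `windowLow`, `windowHigh` | 430.1, 971.5 nm | analysis window (closed interval) |
| `nTrain` | 73 | Kennard–Stone training-set size |
| `hccK` | 100 | bands kept by correlation ranking |
| `spaSizes` | 5–25 | SPA chain lengths scanned by LOO RMSE |
| `gaKMax`, `gaGenerations`, `gaPopSize` | 20, 100, 50 | GA size cap / iterations / population |
| `qMax` | 20 | largest component count scanned |
| `sigma` | 50 | Gaussian kernel bandwidth, reflectance scale |
| `masterSeed` | 1 | drives simulation and GA reproducibly |

σ = 50 is kept on the raw reflectance scale (values in [0, 1]); because the
appropriate bandwidth depends on any preprocessing applied, it is exposed as
a parameter rather than hard-coded.

### Selection details

* **HCC** ranks bands by |Pearson correlation| with the trait — negative
  correlations are as informative as positive ones — with ties broken
  toward the lower band index, and is computed per trait on training data
  only (computing it on all seeds would leak test labels into selection).
* **SPA** grows a chain of minimally collinear bands: each step adds the
  column with the largest norm after projection onto the orthogonal
  complement of the selected set. The chain start and length are chosen by
  leave-one-out RMSE of an OLS model on the selected bands (PRESS
  shortcut). Chain length is capped at min(n, p), the geometric limit of
  the projection sequence.
* **GA** searches binary band masks (tournament size 3, uniform crossover
  0.8, bit-flip mutation 2/p, elitism 1, best-ever returned). Its fitness
  is the leave-one-out cross-validated correlation of an OLS model on the
  masked bands, penalized 0.01 per band above `gaKMax`; LOO comes free from
  the hat matrix, so a mask costs one QR decomposition. The reference
  procedure names the trait itself as "the fitness function"; predictive CV
  performance for that trait is the only reading that yields a maximizable
  scalar, and is what is implemented.

## The synthetic study generator

No per-seed dataset accompanies the reference procedure, so the package
ships a generator with known ground truth; every downstream stage is tested
as a parameter-recovery problem.

Each seed's spectrum is a smooth baseline — a shared seed-like reflectance
shape rising through the VNIR with a broad water dip near 980 nm, plus
per-seed albedo, slope and curvature deviations — with Gaussian
band-localized perturbations at designated informative bands. The per-seed
perturbation amplitudes are the latent variables: each trait is a linear
predictor over the spectrum values at its informative bands, passed through
a link, plus Gaussian noise, truncated at zero (lengths are nonnegative;
truncations are counted and reported). The default study uses 89 seeds and
256 bands over 386.7–1016.7 nm on a uniform grid — the real instrument's
slightly irregular 3 nm grid is unpublished, and a uniform grid keeps
fixtures reproducible; the closed default window then holds 219 bands.

The two traits deliberately differ, emulating the qualitative pattern that
root length is the better-predicted trait: root length loads on mid/high
wavelengths (≈705, 810, 900 nm) with larger effects and less noise;
seedling length loads on low wavelengths (≈470, 520, 560 nm) with smaller
effects and more noise.

**The nonlinear link.** The default link is an offset scaled logistic,
`intercept + scale * plogis(gain * (z - center)) + noise`, with the
midpoint `center` placed above the population mean of the standardized
predictor z. Biologically this is a saturating growth response in which
vigorous seeds plateau while weak seeds spread out. Numerically the offset
matters: between-seed squared spectral distances in this regime are a few
units, so at σ = 50 the Gaussian kernel is close to linear and its leading
nonlinear capacity is quadratic; a *symmetric* logistic leaves a mostly
cubic residual that neither linear models nor the kernel can fit, whereas
the offset logistic leaves a strong quadratic residual that KPCR captures
and the linear models cannot. The link parameters were chosen once so that
the kernel model's advantage on the default study is decisive rather than
marginal — this is the intended study condition, mirroring the finding the
pipeline exists to reproduce — and were frozen before being asserted on a
fixed seed.

For parameter-recovery checks (can HCC/SPA/GA find the truly informative
bands?) the generator is used with near-discrete informative features:
narrow perturbations (sub-band width) and a per-band noise floor, so that
neighboring bands are genuinely attenuated copies rather than statistical
ties. The recovery experiment uses n = 200 seeds, 50 bands, 3 informative
bands, and trait noise set for a 5:1 signal-to-noise variance ratio, over
20 seeded replicates — large enough for stable rates, small enough to run
in about a minute.

**What the generator does not emulate:** sensor point-spread, spectral
smile/keystone, illumination falloff, seed-shape realism beyond ellipses,
spatial within-seed heterogeneity (cube fixtures give every ROI pixel the
seed's spectrum, making calibration round-trips exact), or between-band
noise correlation. Passing tests therefore demonstrate correctness of the
algorithms and the qualitative orderings under the stated latent structure,
not instrument-level realism.

## Numerical choices and degenerate inputs

* Calibration pixels with `white == dark` have no defined reflectance; they
  are masked (NA), excluded from ROI means, and an ROI fully masked at some
  band is an error. Silent NaN propagation would corrupt every downstream
  regression. Reflectance outside [0, 1] (specular highlights) is kept and
  logged, never clipped.
* Pixel membership is pixel-center-in-ellipse with 0-based (x = column,
  y = row) coordinates.
* Eigen/singular vectors have their sign fixed so the largest-magnitude
  entry is positive, making serialized models reproducible across LAPACK
  builds; predictions are sign-invariant regardless.
* Kennard–Stone, HCC and SPA break ties toward the lower index; duplicate
  samples (zero distances) proceed under the tie rule with a warning.
* A constant trait is a hard error for selection and PLS ("degenerate
  target"); constant *predictions* score CC = 0 with a warning so a
  degenerate model ranks last without aborting the comparison grid.
* PCR requests above the numerical rank are truncated with a warning; the
  GA falls back to the best single band if its best mask is ever empty.
* Failures of individual grid cells (e.g. a degenerate selection) are
  recorded in-grid with a message and do not abort the experiment — a
  comparative report needs the surviving cells.

## Problem sizes used by the checks

The shipped checks run the full default study (89 seeds × 256 bands, 73/16
split, 24-cell grid, ≈10 s), the 20-replicate recovery experiment
(n = 200 × 50 bands, ≈80 s, dominated by the GA), and small oracle
instances (n ≤ 30, p ≤ 10) for the exact equivalences against least
squares. These sizes are the package's chosen test conditions; the
functions themselves scale to larger cubes and grids.

## Known limitations

* Seed ROIs must be supplied (or generated); there is no automatic seed
  segmentation.
* Only univariate-response models are implemented (no PLS2, no kernel PLS),
  and no uncertainty quantification is attached to the grid cells.
* The 16-seed test partition of the default study makes single-split CC
  estimates noisy; conclusions about model orderings in real studies should
  use repeated splits or cross-validation rather than one grid.
* Whether modeling should use whole-seed or embryo/endosperm sub-ROIs is
  left to the user (`part` column in the ROI table); the default is
  whole-seed.
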