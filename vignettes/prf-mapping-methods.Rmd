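---
title: "Population receptive field mapping: model, stimuli, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population receptive field mapping: model, stimuli, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfmap)
```

## Overview

`prfmap` implements a complete, self-contained workbench for population
receptive field (pRF) mapping with fMRI: generation of the classical
mapping stimuli (drifting bars, simultaneous wedge-and-ring, full-field
photic bursts), the 2D-Gaussian forward model and its two-stage
coarse-to-fine estimation, per-subject estimation of the hemodynamic
response function (HRF), the traveling-wave (phase-encoded) analysis,
cross-validated model comparison, and downstream summaries
(size-eccentricity curves, slope comparisons, model-versus-phase
eccentricity comparison).

Because no human data ship with the package, everything is validated
against a synthetic cortical sheet with known ground truth. The synthetic
generator is not an afterthought: its defaults *are* the study
conditions, and the test suite and `scripts/acceptance.R` quantify how
well the estimation machinery recovers what the generator constructed.

This vignette explains the model, the main parameter choices and their
rationale, the design of the synthetic generator, and the numerical
decisions that matter for reproducing the results. It asserts no
empirical number that the test suite or the acceptance script does not
itself compute.

## The encoding model

Each imaging unit (vertex) is modeled as a 2D isotropic Gaussian in
visual space with center $(x_0, y_0)$ (degrees of visual angle), spread
$\sigma$ (degrees), and amplitude $\beta$:

$$ w(x, y) = \exp\!\left(-\frac{(x - x_0)^2 + (y - y_0)^2}{2\sigma^2}\right). $$

The stimulus at volume $t$ is summarized by a binary aperture mask
$m_t(x, y)$ on a pixel grid; the predicted neural response is the sum of
Gaussian weights inside the aperture,

$$ n(t) = \sum_{x,y} m_t(x, y)\, w(x, y), $$

which is convolved with the HRF and scaled by $\beta$ to produce the BOLD
prediction. Blank (mean-luminance) volumes therefore predict exactly
zero — blanks anchor the model's baseline, which is what makes large
pRFs estimable at all.

The HRF is a difference of two gamma-shaped bumps with exactly three free
parameters — response peak delay, undershoot peak delay, and the
response:undershoot amplitude ratio:

$$ h(t) = g(t; d_1) - g(t; d_2)/r, \qquad
   g(t; d) = (t/d)^s \exp\!\big(-s\,(t - d)/d\big), $$

with the shape exponent fixed at $s = 5$ so that each bump has unit peak
at $t = d$. Under this parameterization the free delays *are* the peak
times, which keeps the estimates directly interpretable; overall
amplitude is a nuisance parameter profiled out by linear least squares.
Defaults (6 s, 16 s, ratio 6) are standard textbook values; per-subject
estimation from the photic run replaces them in the full pipeline.

## Stimuli

All stimuli share a dynamic high-contrast carrier (a rippling
pseudo-checkerboard, rectified to a binary pattern, one phase cycle every
1.152 s) viewed through condition-specific apertures that advance once
per acquired volume (TR = 2.55 s). Only the binary aperture enters the
model; the carrier is generated for completeness and inspection.

* **Size-invariant bars** (`bar_sequence(scaled = FALSE)`): a bar of
  constant width (2.70° at the 16°-radius reference display, scaled
  proportionally for other display sizes) sweeps the display diameter in
  24 volumes. A run is two trials of [sweep, orthogonal sweep, 24-volume
  blank] — 144 volumes, 48 of them blank.
* **Logarithmically scaled bars** (`scaled = TRUE`): identical timing,
  but the bar width follows the cortical-magnification-inspired map
  $e(u) = e_{\min} (e_{\max}/e_{\min})^{u}$ with $e_{\min} = 0.06°$,
  evaluated at the bar center's normalized eccentricity — very narrow at
  fixation, display-filling at the edge.
* **Wedge and ring** (`wedge_ring_sequence`): an 18°-wide wedge rotating
  one revolution per 20 volumes (6 cycles per run) shown simultaneously
  with an annulus stepping through 15 log-spaced positions per cycle
  (8 cycles per run), adjacent annuli overlapping by half of their radial
  log-domain extent; 120 stimulation volumes then one terminal 24-volume
  blank.
* **Photic bursts** (`photic_sequence`): the full stimulated disc for one
  volume followed by 11 blanks, ten times — the HRF estimation run.

A full session (`session_schedule`) is ten 144-volume runs (four
invariant-bar, four log-bar, two wedge-ring) totaling 1440 volumes.

Two stimulus-geometry readings deserve mention. The wedge advances 18°
per volume (20 volumes per revolution), i.e. adjacent wedge positions
abut rather than overlap; run timing is treated as authoritative over
any nominal overlap. And the bar's traverse is center-aligned: the bar
center moves from $-R$ to $+R$ in 24 equal steps starting half a step
inside the edge, so coverage is symmetric.

## Two-stage fitting

1. **Smoothing.** Data are smoothed along the cortical sheet
   (8.3 mm FWHM before coarse fitting; 5 mm before phase-encoded
   analysis). Smoothing uses a Gaussian kernel in geodesic (graph)
   distance, *Sinkhorn-balanced to a doubly stochastic matrix*. A merely
   row-normalized kernel leaks mass at sheet boundaries; the doubly
   stochastic version passes constants through unchanged and preserves
   the spatial mean of every time point to machine precision, which the
   test suite checks.
2. **Coarse stage.** An exhaustive correlation search over a fixed
   candidate grid: centers on a 2.4° lattice within the display bounds,
   crossed with 34 exponentially spaced $\sigma$ values from 0.32° to
   32°. Correlation is scale-free, so candidates need no amplitude.
   Candidates are ordered by $\sigma$ then center eccentricity, making
   the argmax tie-break deterministic (smallest $\sigma$, most foveal
   center first). Vertices whose best correlation is not positive or
   whose $r^2 \le 0.05$ are excluded.
3. **Fine stage.** Nelder-Mead minimization of squared residuals over
   $(x_0, y_0, \sigma, \beta)$ on the *unsmoothed* series, started at the
   coarse candidate with $\beta$ initialized by least-squares projection.
   Non-positive $\sigma$ is repelled with an infinite objective. The
   reported goodness of fit is $R^2 = 1 - SS_{res}/SS_{tot}$; analyses
   threshold at $R^2 > 0.1$ (strict). If the simplex fails to converge,
   the starting values are retained and flagged, rather than returning a
   partially optimized state.

## Phase-encoded analysis

For the wedge-and-ring runs, each vertex's discrete Fourier coefficient
is taken at exactly 6 cycles/run (wedge) and 8 cycles/run (ring) after
removing the terminal blank; the two frequencies are orthogonal over the
120 stimulation volumes, so the composite stimulus can be analyzed once
for both maps. Opposite-direction runs are combined by negating the
reversed-run phase and circularly averaging, which cancels the common
hemodynamic lag. Combined phase is converted to cycle progress and
decoded: wedge progress maps linearly to polar angle (start 90°,
clockwise), ring progress maps through the same logarithmic eccentricity
schedule that generated the rings, so phase 0 decodes to $e_{\min}$ and
half a cycle to the geometric mean of the range.

The package's phase/pRF comparison (`compare_ecc_estimates`) normalizes
both estimates by the display radius before comparing — the discrepancy
between the two methods is a function of *relative*, not absolute,
eccentricity, which the acceptance checks verify across simulated 9° and
16° displays. The phase-encoded side is thresholded on
coherence-squared (fraction of variance at the ring fundamental), since a
phase map has no regression $R^2$.

## The synthetic cortical sheet

`make_sheet` lays vertices on a stacked regular grid (one block per
region, 2 mm spacing, 4-connected, always one connected component), maps
one grid axis to log-spaced eccentricity and the other to uniform polar
angle, applies a small seeded jitter, and assigns each vertex a
ground-truth Gaussian pRF whose size follows the region's linear law
$\sigma = a + b \cdot ecc$ computed from the jittered eccentricity — so
the constructed law holds exactly, by design. Realistic default laws are
V1-like ($0.5 + 0.25\,ecc$) and V3-like ($1.5 + 0.35\,ecc$), in the range
reported across human retinotopic cortex.

`simulate_bold` runs the forward model generatively and adds Gaussian
noise, optionally AR(1)-correlated in time, calibrated per vertex so that
the noiseless prediction's peak divided by the noise SD equals the
requested contrast-to-noise ratio (CNR). CNR 3 is used as the reference
condition for recovery experiments and CNR 2 for HRF estimation — values
chosen as representative of single-run cortical fMRI. What the generator
deliberately omits: physiological noise structure, spatial noise
correlations, vascular delay gradients, and true surface geometry (the sheet
is flat; smoothing distances are graph distances). Recovery numbers
should therefore be read as upper bounds on real-data performance.

A difference-of-Gaussians (DoG) variant (`make_dog_truth`) subtracts a
wider surround (default ratio 2, relative amplitude 0.2) from each
center Gaussian. These defaults describe a moderate, net-excitatory
surround: when $amp \times ratio^2 \ge 1$ the integrated surround cancels
the integrated center and the full-field response becomes non-positive —
a degenerate regime the constructor warns about, and near which (e.g.
$amp \times ratio = 1$) a thin bar crossing the pRF center evokes no
response at all. The DoG sheet exists to probe how fitting a *plain*
Gaussian to center-surround data biases $\sigma$ estimates differently
under different aperture configurations: stimuli that frequently fill
the surround (wide peripheral log-scaled bars) depress the apparent
response at wide extents and yield smaller $\hat\sigma$ than
size-invariant bars. The acceptance suite tests exactly this direction.

## Numerical choices

* **Rendering resolution.** Tests and the acceptance script render at
  2 px/deg (and 1–1.5 px/deg where geometry alone is at stake). The model
  integrates Gaussians over many pixels, so resolution affects runtime
  far more than accuracy; the resolution is a compute choice, not a
  scientific one.
* **Convolution.** Causal convolution is FFT-based (`stats::convolve` /
  `stats::mvfft` with power-of-two padding), truncated to run length and
  applied per run, never across run boundaries. HRF kernels sampled
  finer than the TR are handled by exact integer up-sampling.
* **Optimizer settings.** Nelder-Mead with relative tolerance $10^{-4}$
  and an iteration cap of 400 per free parameter. The HRF fit uses a
  small multi-start over response-delay initializations (4, 6, 8 s) to
  avoid the local minimum where the response bump locks onto the
  undershoot.
* **Determinism.** Every stochastic step takes an explicit seed and
  restores the caller's RNG state; pipeline stages derive their seeds
  from one global seed.

## Scope and limitations

The package fits isotropic Gaussians only; center-surround and
compressive-summation models appear solely as generators, not as
estimable models. Cortical surface geometry is approximated by a flat
graph. The statistical helpers (paired t-tests on Fisher-z scores and
slopes, repeated-measures ANOVA on goodness of fit) are deliberately
classical reporting machinery. Reported recovery quality is conditional
on the generator's noise model; none of the validation numbers are claims
about human data.

## Reproducing the validation

The full validation is executable:

```r
# unit + property + acceptance tests, from a source checkout
testthat::test_dir("tests/testthat", package = "prfmap")
```

(or `Rscript -e 'devtools::test()'`). The
headline quantities (design arithmetic, recovery errors, slope
differences, phase bias, HRF errors, DoG bias) are recomputed and written
as JSON by:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
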