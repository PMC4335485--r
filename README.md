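# prfmap

Population receptive field (pRF) mapping of retinotopic visual cortex
from fMRI time series, with configurable stimulus designs and a fully
synthetic validation bed.

A population receptive field summarizes the region of the visual field
that drives an imaging unit (voxel or surface vertex): it is modeled
here as a 2D isotropic Gaussian with center `(x0, y0)`, spread `sigma`
(all in degrees of visual angle) and amplitude `beta`. The predicted
neural response to a stimulus frame is the Gaussian mass inside the
stimulus aperture; convolving that with a double-gamma hemodynamic
response function (HRF) yields the BOLD prediction that is fitted to the
measured series. How well the fitted parameters — in particular the
canonical linear increase of pRF size with eccentricity — can be
recovered depends strongly on *which* stimulus configuration was shown,
and comparing configurations is what this package is built for.

## What the package provides

* **Stimuli** (`stimulus_design`, `bar_sequence`, `wedge_ring_sequence`,
  `photic_sequence`, `session_schedule`): frame-accurate binary apertures
  for size-invariant drifting bars, eccentricity-scaled (logarithmic)
  bars, a simultaneous rotating-wedge + expanding-ring configuration,
  and full-field photic bursts for HRF estimation, on top of a dynamic
  high-contrast carrier. A full session is ten 144-volume runs
  (TR = 2.55 s, 1440 volumes).
* **Forward model** (`gaussian_prf`, `bold_prediction`, `double_gamma`):
  Gaussian pRF encoding, unit-peak double-gamma HRF with three free
  parameters, causal FFT convolution respecting run boundaries.
* **Fitting** (`build_search_grid`, `fit_prf`): geodesic smoothing on the
  cortical sheet (doubly stochastic, mean-preserving), exhaustive
  coarse correlation search, Nelder-Mead refinement, `R^2`
  goodness of fit.
* **HRF estimation** (`estimate_hrf`): trial-averaged responses to the
  photic run with outlier rejection, fitted per subject.
* **Phase-encoded analysis** (`phase_encode`): traveling-wave polar-angle
  and eccentricity maps from opposite-direction wedge-ring runs, with
  hemodynamic-lag cancellation, plus a model-vs-phase eccentricity
  comparison (`compare_ecc_estimates`).
* **Cross-validation and summaries** (`predict_heldout`,
  `fisher_z_scores`, `sigma_ecc_slope`, `bin_sigma_by_eccentricity`,
  `gof_anova`): condition-to-condition generalization on Fisher-z
  correlation scores and classical statistics on size-eccentricity
  relationships.
* **Synthetic ground truth** (`make_sheet`, `make_dog_truth`,
  `simulate_bold`): a connected cortical sheet with exact, constructed
  retinotopy and size-eccentricity laws, Gaussian or
  difference-of-Gaussians pRFs, and CNR-calibrated AR(1) noise. Every
  quantitative claim in the package is validated against this generator.
* **Pipeline and I/O** (`pipeline_config`, `run_pipeline`, plus a thin
  CLI at `inst/cli/prfmap.R`): a staged, manifest-writing pipeline with
  YAML configuration and plain-text artifact formats.

## Worked example

Simulate a V1-like sheet of 100 vertices, run two bar runs at
contrast-to-noise ratio 3, fit the pRF model, and summarize pRF size
against eccentricity.

```r
library(prfmap)

# 1. Stimuli: a reduced-resolution 9-degree display
cfg <- carrier_config(max_ecc_deg = 9, pixels_per_degree = 2)
design <- stimulus_design()
runs <- session_schedule(design, cfg)
print(runs$bar_card_fwd)
print(attr(runs, "total_volumes"))

# 2. A synthetic cortical sheet with known ground truth
sheet <- make_sheet(100, rois = list(roi_spec("V1", 0.5, 0.25)),
                    max_ecc = 9, seed = 1)
print(sheet)
head(sheet$truth[, c("x0", "y0", "sigma", "ecc")], 3)

# 3. Simulate a bar session at CNR 3 and fit
hrf <- hrf_params(dt = 2.55)
bar_runs <- runs[c("bar_card_fwd", "bar_obli_fwd")]
dat <- simulate_bold(sheet, bar_runs, hrf, noise_spec(cnr = 3, seed = 2))
grid <- build_search_grid(bar_runs, hrf)
fits <- fit_prf(dat, sheet, grid)
ok <- fits$included & fits$converged %in% TRUE
cat(sprintf("fitted %d/%d vertices\n", sum(ok), nrow(fits)))
cat(sprintf("median center error: %.2f deg\n",
            median(sqrt((fits$x0[ok] - sheet$truth$x0[ok])^2 +
                        (fits$y0[ok] - sheet$truth$y0[ok])^2))))
cat(sprintf("median relative sigma error: %.1f%%\n",
            100 * median(abs(fits$sigma[ok] - sheet$truth$sigma[ok]) /
                         sheet$truth$sigma[ok])))

# 4. Size-eccentricity summary on thresholded fits
thr <- threshold_fits(fits, r2_min = 0.1)
curve <- bin_sigma_by_eccentricity(thr, bin_deg = 2, max_ecc = 9)
print(curve[, c("bin_mid", "mean_sigma", "n_subjects")], row.names = FALSE)
```

Output:

```
<aperture_sequence> bar_invariant (0/90 deg, sign +1): 144 volumes (48 blank), TR 2.55 s, 1369 px
[1] 1440
<cortical_sheet> 100 vertices, 1 region(s), max ecc 9 deg
         x0        y0     sigma       ecc
1 0.4728013 0.1423805 0.6234436 0.4937745
2 0.6577157 0.2147743 0.6729736 0.6918944
3 0.8976632 0.2604242 0.7336691 0.9346764
fitted 100/100 vertices
median center error: 0.21 deg
median relative sigma error: 12.6%
 bin_mid mean_sigma n_subjects
       1  0.8026551          1
       3  1.1949284          1
       5  1.6878069          1
       7  2.0897264          1
       9  2.7871848          1
```

The binned means increase with eccentricity as constructed
(`sigma = 0.5 + 0.25 * ecc`), and the fitted centers land within a
fraction of a degree of truth at this noise level.

The staged pipeline wraps the same steps end to end:

```r
cfgp <- pipeline_config(seed = 1)
run_pipeline(cfgp, stages = c("stimuli", "simulate", "hrf", "prf", "report"),
             out_dir = "out")
```

or from the shell:

```sh
Rscript inst/cli/prfmap.R --stages stimuli,simulate,hrf,prf,report --out out --seed 1
```

## License

MIT (see `LICENSE`).
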