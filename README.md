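# usbeam — adaptive minimum-variance beamforming for synthetic ultrasound

`usbeam` is an R toolkit for medical ultrasound image formation research:
it simulates RF channel data for a linear transducer array, beamforms it
into B-mode images, and scores the images with standard quality metrics.
It is aimed at people developing or teaching adaptive (Capon-family)
beamformers who need a controlled, fully reproducible synthetic testbed
rather than a clinical scanner.

## The algorithms

Given the aligned (receive-focused) snapshot $s \in \mathbb{C}^M$ of an
$M$-element array and a steering vector $\lambda$, the minimum-variance
distortionless response (MVDR / Capon) beamformer solves

$$\min_w \; w^H F w \quad \text{s.t.} \quad w^H \lambda = 1
\;\Longrightarrow\;
w = \frac{F^{-1}\lambda}{\lambda^H F^{-1} \lambda},$$

with $F$ the interference-plus-noise covariance estimated by sliding
subapertures of length $L$, temporal averaging, and diagonal loading.
The package's robust pipeline (`iscb_weights()`, method `"ISCB"`) adds:

1. **forward–backward correction** $F' = F + K\overline{F}K$ ($K$ the
   exchange matrix) — enforces persymmetry and decorrelates coherent
   echoes;
2. **eigen split** of $F'$ at 0.5 × the largest eigenvalue into signal
   ($W_s, \Pi_s$) and noise subspaces;
3. **steering correction**
   $\min_\lambda \lambda^H W_s \Pi_s W_s^H \lambda$ subject to
   $\lVert\lambda-\bar\lambda\rVert^2 \le \tau$, solved in closed form in
   the signal eigenbasis with the Lagrange multiplier found by bisection;
4. Capon weights on $F'$ with the corrected, $\sqrt{L}$-normalized
   steering.

Baselines: DAS (uniform weights), SCB (plain Capon), RLS (recursive
least squares with forgetting factor), SER (projected
stochastic-gradient sequential regression). Metrics: time-averaged power
$P = \frac{1}{T}\int_0^T |s(t)|^2 dt$, region powers in dB re. image
peak, anechoic-cyst contrast $|P_{bg} - P_{ctr}|$, lateral −6 dB FWHM
resolution, and peak sidelobe level. The methods vignette
(`vignettes/adaptive-beamforming.Rmd`) derives and discusses everything,
including the one deliberately surprising property of the steering
correction.

## Worked example

Point target at 25 mm depth, 64-element 5 MHz array, −30 dB channel noise:

```r
library(usbeam)
geom  <- make_linear_array(64, 0.154, 5e6, 40e6)
pulse <- make_pulse(5e6, 0.6, 4)
cd    <- simulate_channel_data(geom, make_point_phantom(0, 25), pulse,
                               noise_db = -30, seed = 1)
grid  <- make_image_grid(seq(-1.5, 1.5, by = 0.05), seq(24.8, 25.2, by = 0.1))
imgs  <- beamform_methods(cd, grid, c("DAS", "SCB", "ISCB"))
sapply(imgs, function(im) lateral_fwhm(im, c(0, 25)))
#>        DAS        SCB       ISCB
#> 0.95664492 0.05446700 0.05236747
```

The adaptive beamformers narrow the point spread from ~0.96 mm (the
diffraction-limited DAS width at this depth/aperture) to ~0.05 mm.
The standardized multi-seed comparison (anechoic cyst for contrast, point
target for resolution):

```r
res <- benchmark_report(c("DAS", "SCB", "ISCB"), n_seeds = 10, seed = 1)
res$medians
#>   method center_power_db background_power_db contrast_db resolution_fwhm_mm peak_sidelobe_db
#> 1    DAS       -27.88234           -12.88314    14.06760         0.95642031        -19.69407
#> 2    SCB       -33.19459           -14.09873    19.14927         0.03305747        -27.63553
#> 3   ISCB       -33.21003           -14.82963    18.70258         0.02893519        -31.22677
```

Reading the table: ISCB has the lowest center and background powers, the
best (smallest) resolution and the lowest sidelobes; its median cyst
contrast sits a fraction of a dB below SCB's — a systematic property of
the printed steering-correction direction, analyzed in the vignette and
asserted honestly (one failing expectation) in the acceptance tests.

## Command line

`inst/cli/usbeam.R` wraps the pipeline (requires `optparse`):

```sh
Rscript inst/cli/usbeam.R simulate  --config cfg.json --out data.json
Rscript inst/cli/usbeam.R beamform  --data data.json --method ISCB --out img.pgm --image img.json
Rscript inst/cli/usbeam.R metrics   --data data.json --method ISCB --out metrics.csv
Rscript inst/cli/usbeam.R benchmark --config cfg.json --out report.csv
Rscript inst/cli/usbeam.R render    --image img.json --out img.pgm --dynamic-range 50
```

Configuration is JSON (see `inst/extdata/example_config.json` and
`default_run_config()`); unknown keys are rejected and every violation is
reported at once. Every artifact gets a `.provenance.json` sidecar echoing
the resolved configuration, package version and seed. File formats are
deliberately all text: channel data and complex images are JSON array
containers written at full precision (`write_channel_data()` documents the
structure, so third-party data can be converted in), B-mode images are
ASCII PGM, reports are CSV — identical runs are byte-identical, and the
test suite checks exactly that.

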