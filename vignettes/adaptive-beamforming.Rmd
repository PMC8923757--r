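---
title: "Adaptive minimum-variance beamforming for synthetic ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive minimum-variance beamforming: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usbeam)
```

## What this package computes

`usbeam` is a simulate → beamform → render → score toolkit for B-mode
ultrasound image formation with a linear transducer array. Its scientific
core is a robust variant of the Capon (minimum-variance distortionless
response, MVDR) beamformer that combines three corrections:

1. **forward–backward (Toeplitz) covariance correction** of the
   interference-plus-noise covariance estimate,
2. an **eigenvalue-threshold split** of the corrected covariance into
   signal and noise subspaces, and
3. a **quadratically constrained steering-vector correction** solved by a
   Lagrange multiplier.

The package calls this pipeline ISCB (improved standard Capon beamformer)
and evaluates it against non-adaptive delay-and-sum (DAS), the standard
Capon beamformer (SCB), and two classical sequential baselines (RLS and
SER) on synthetic phantoms, using four image-quality figures: center and
background region power, contrast, and lateral resolution (−6 dB FWHM),
plus a peak-sidelobe figure.

## Signal model and focusing

The array is a 1-D linear aperture of $M$ elements at pitch $p$ (default:
$M = 64$, half-wavelength pitch $0.154$ mm at $f_0 = 5$ MHz in
$c = 1540$ m/s tissue, sampled at 40 MHz; a 5 MHz carrier sits inside the
4–8 MHz band typical of abdominal/pelvic probes). The forward model is
deliberately the simplest one that exercises every beamformer identically:
monostatic pulse-echo with a plane wave launched from the aperture plane, a
Gaussian-modulated sinusoid pulse, $1/r$ spherical spreading, no
frequency-dependent attenuation, and additive white Gaussian channel noise
quoted in dB relative to the peak signal amplitude. A scatterer of
amplitude $a$ at $(x, z)$ contributes to element $m$ a pulse replica at the
two-way time $(z + r_m)/c$ with amplitude $a/r_m$. Simulation is exactly
linear in the phantom and bit-reproducible under a seed; both properties
are asserted by tests.

Receive focusing is dynamic (per pixel): for a focal point the element
delays are $\Psi_m = (r_m - \min_m r_m)/c \ge 0$. One notational point is
worth making explicit: the conventional shorthand for the focused snapshot,
$p_m(t - \Psi_m)$, aligns channels only if $t$ is read per element; with
nonnegative delays normalized to $\min \Psi = 0$ the aligned sample of
channel $m$ is at $t + \Psi_m$ (an advance relative to the
nearest-element arrival $t$). The package implements the advance, so that a
point target at the focus yields $M$ equal snapshot entries — the testable
contract. Fractional sample positions use linear interpolation, adequate at
the 8× carrier oversampling of the defaults (worst-case droop ≈ 2%); a
spline upgrade would be contract-compatible.

## Covariance estimation

Adaptive weights need an interference-plus-noise covariance $F$. The
estimator is standard ultrasound subaperture practice: sliding windows of
length $L$ across the aperture (spatial smoothing restores rank against
coherent speckle), outer products averaged additionally over a temporal
window of $2h+1$ snapshots centered on the pixel's arrival time, plus
diagonal loading $\epsilon \, \mathrm{tr}(F)/L \cdot I$. Defaults and
rationale:

* $L = \lfloor M/2 \rfloor$ — the usual compromise between interference
  rejection (large $L$) and estimate robustness/decorrelation (small $L$);
* $h = \mathrm{round}(2 f_s / f_0)$ samples (≈ half the default 4-cycle
  pulse, so the temporal window spans about one pulse length);
* $\epsilon = 1/(100 L)$ — light loading that guarantees invertibility
  without biasing the adaptive pattern noticeably.

All-zero snapshot sets are rejected with an error rather than silently
returning a zero matrix.

The forward–backward correction is applied exactly as the underlying
method prescribes,

$$F' = F + K \, \overline{F} \, K,$$

with $K$ the exchange (anti-diagonal) matrix and $\overline{F}$ the
elementwise conjugate. The sum is deliberately **not** halved: Capon
weights are invariant to any positive rescaling of the covariance, so the
conventional $\tfrac12$ cannot change a single beamformer output — the
package proves this by test rather than normalizing silently. $F'$ is
Hermitian and persymmetric ($K \overline{F'} K = F'$), and PSD inputs stay
PSD (sum of two PSD terms).

## Eigen split and steering-vector correction

$F'$ is eigendecomposed and partitioned at a threshold of
`threshold_factor` × the largest eigenvalue (default 0.5): eigenvalues at
or above the threshold span the signal(+interference) subspace
$W_s, \Pi_s$, the rest the noise subspace. Ties go to the signal side (the
"greater than" of the underlying description leaves ties measure-zero; the
package uses ≥ so the maximum always qualifies and $k \ge 1$).

The steering correction solves

$$\min_\lambda \; \lambda^H A \lambda
  \quad \text{s.t.} \quad \lVert \lambda - \bar\lambda \rVert^2 \le \tau,
  \qquad A = W_s \Pi_s W_s^H,$$

whose stationarity condition gives $\lambda(\beta) = (I + A/\beta)^{-1}
\bar\lambda$. In the signal eigenbasis, with $a = W_s^H \bar\lambda$, the
constraint residual

$$d(\beta) = \sum_i |a_i|^2 \left( \frac{\pi_i}{\beta + \pi_i} \right)^2$$

is strictly decreasing in $\beta$, so the multiplier is found by bisection
(`uniroot` on $\log \beta$, bracket $[10^{-12}, 10^{12}] \times
\pi_{\max}$, tolerance $10^{-13}$ — convergence is guaranteed by
monotonicity). Degenerate cases short-circuit: $\tau = 0$ or $A\bar\lambda
= 0$ return $\bar\lambda$; if the unconstrained minimizer (projection of
$\bar\lambda$ onto the orthogonal complement of $W_s$) already satisfies
the constraint it is returned with $\beta = 0$. The corrected vector is
renormalized to $\lVert \lambda \rVert = \sqrt{L}$ before the Capon solve —
the correction introduces a scale ambiguity, and this is standard
robust-Capon practice. $\tau$ defaults to $0.1 L$.

**A consequence worth understanding.** The optimization direction is
*minimization* of the signal-subspace projection — that is what the
worked example $A = \mathrm{diag}(1,0)$, $\bar\lambda = (1,1)$,
$\tau = 0.25 \Rightarrow \lambda = (0.5, 1)$ pins down, and what the
package implements and verifies against dense grid search. Minimizing that
projection necessarily *shrinks* the component of $\lambda$ along the
dominant eigenvector. Two implications:

* In regions where the dominant eigenvector *is* the true steering (bright
  speckle, a strong on-axis source), the corrected steering tilts *away*
  from the truth; a "recovered steering is closer to the true steering"
  property cannot hold under this reading and is not asserted.
* On an anechoic-cyst phantom the correction lowers the background speckle
  gain slightly (the signal subspace there contains the on-axis speckle
  signal) while being nearly neutral inside the cyst (flat eigenvalue
  spectrum, so many eigenvalues clear the 0.5 threshold and the correction
  spreads thin). Background power drops — but cyst *contrast*
  (background − center, in dB) can dip marginally below plain SCB whenever
  SCB itself suffers little coherent signal cancellation, which is the case
  under the defaults here ($L = M/2$ smoothing plus pulse-length temporal
  averaging already decorrelate the speckle, leaving the forward–backward
  step little to recover). The acceptance suite measures exactly this: on
  the standardized phantom ISCB achieves the lowest background power,
  lowest center power, best resolution and lowest sidelobes of
  {DAS, SCB, ISCB}, while its median contrast lands a fraction of a dB
  below SCB's. The contrast expectation is left failing rather than
  papered over; see the repository's decision notes.

The final ISCB weights are the Capon solution on the corrected covariance,
$Z = F'^{-1}\lambda / (\lambda^H F'^{-1} \lambda)$, which satisfies the
distortionless constraint $Z^H \lambda = 1$ by construction.

## Baselines

* **DAS** — uniform $1/M$ weights on the full aperture after focusing.
* **SCB** — Capon weights on the loaded, uncorrected covariance.
* **RLS** — textbook recursive least squares: the inverse covariance is
  propagated by the matrix inversion lemma with forgetting factor $\mu$
  (default 0.99) from $P_0 = I/\delta$, Capon-normalized at the end. With
  $\mu = 1$ this is *algebraically identical* to SCB on
  $\delta I + \sum_t x_t x_t^H$, which the tests verify to $10^{-8}$.
* **SER** — sequential regression: projected stochastic-gradient descent
  on the constrained output power, one snapshot per step, with the
  distortionless constraint re-imposed exactly after every step. On white
  noise it converges to the $F = I$ Capon solution
  $\lambda/\lVert\lambda\rVert^2$; the stochastic sampling floor is
  $O(1/\sqrt{n})$, so the limit is verified tightly on an exactly-white
  deterministic stream and loosely on a random one.

These two are labeled *baselines in their standard literature forms*; the
source material names them without defining them.

## Imaging and metrics conventions

Per pixel, adaptive outputs are subaperture-averaged:
$Q = \frac{1}{G}\sum_{g} w^H s_g$ over the $G = M - L + 1$ sliding windows
of the central snapshot. Envelope detection is the magnitude of the
analytic signal (FFT Hilbert construction); display is
$20\log_{10}(|Q|/\max|Q|)$ clipped at a default 60 dB dynamic range, with
the peak at exactly 0 dB. PGM rendering maps 0 dB → 255 and
$-\mathrm{DR}$ → 0 affinely with banker's rounding (a −20 dB pixel at
40 dB range maps to 127.5 → 128).

Power metrics use $10\log_{10}$ of the mean *squared* envelope referenced
to the image's global maximum; amplitude displays use $20\log_{10}$.
Because the source material reports "center average power" below
"background average power" without defining regions, the package adopts
the anechoic-cyst convention and documents it as a convention, not a
reproduction: center = disc of 0.6 × cyst radius at the cyst center,
background = a speckle rectangle clear of the cyst, contrast = the
absolute dB difference (so larger = better clutter rejection, invariant to
global rescaling). "Resolution" is operationalized as the −6 dB lateral
FWHM in mm (smaller = better); where a directionally aligned "score" is
wanted, use 1/FWHM. Identical center/background regions give contrast 0 by
definition; partially overlapping regions are an error.

## The synthetic world — and what a green test does not establish

The generator emulates: fully developed speckle (Poisson-distributed
scatterer positions, Rayleigh amplitudes of unit mean, default
4 scatterers/mm², an anechoic disc with zero diffuse scatterers inside),
additive white channel noise (default −30 dB of peak), and isolated point
targets. It does **not** emulate: tissue attenuation or aberration,
elevation focusing, transmit focusing/apodization beyond the plane-wave
assumption, nonlinear propagation, reverberation, or electronic crosstalk.
Green tests therefore establish algorithmic correctness and *relative*
method behavior under idealized conditions — not clinical image quality,
and not the absolute metric values reported for any clinical system
(whose acquisition setup, phantom and metric definitions are not
reproducible from the source material; the standardized numbers here are
properties of this package's stated world only).

## Numerical choices and degenerate inputs

* Hermitian symmetry is enforced by averaging with the conjugate transpose
  before every eigendecomposition; `eigen(symmetric = TRUE)` returns
  descending eigenvalues, which the threshold rule relies on.
* `scb_weights` refuses covariances with `rcond < 1e-12` and points the
  user to diagonal loading.
* All-zero channel data (empty phantom, no noise) is an error at the
  simulator; all-zero snapshot sets are an error at the estimator; all-zero
  images are an error at log compression.
* Seeds: every stochastic step takes an explicit seed and restores the
  caller's RNG state; derived seeds stay below $2^{31}$.
* File formats are text by design (JSON array containers at full precision,
  ASCII PGM images, CSV reports), which makes byte-level determinism of the
  whole pipeline testable — and tested.

## Known limitations

* Pure-R per-pixel loop: a 64-element, ~2,500-pixel, 3-method comparison
  takes a few seconds per realization; the standardized 10-seed benchmark
  takes about a minute. Subaperture stacking and covariance products are
  vectorized; the remaining cost is the per-pixel eigendecomposition.
* Linear interpolation bounds snapshot fidelity at ~2% at 8× oversampling.
* The RLS/SER imaging paths feed the same per-pixel snapshot stream as the
  covariance estimator; their sequential character only matters when the
  stream is long, so their images are close to SCB's under the defaults.
* The contrast behavior of the steering correction discussed above is a
  property of the method as printed, not a tunable of this implementation.
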