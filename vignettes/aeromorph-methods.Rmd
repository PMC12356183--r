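---
title: "Measurement uncertainty in drone-based morphometrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement uncertainty in drone-based morphometrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeromorph)
```

## The measurement problem

A nadir drone image maps the world onto the sensor at a scale set by the
ground sampling distance,

$$GSD = \frac{a}{f}\,\frac{S_w}{I_w},$$

metres per pixel, where $a$ is altitude above the subject (m), $f$ the focal
length (mm), $S_w$ the sensor width (mm) and $I_w$ the image width (px). A
length measured in pixels, $L_p$, converts to metres as $L = GSD \times
L_p$. Camera constants are fixed and (after a focal-length adjustment for
in-camera reprocessing, `adjusted_focal_length()`) known; the altitude is
not. Barometric altimeters are zeroed at launch, drift with weather, and
need the recorded launch height added back; LiDAR altimeters are far more
accurate but return null values over water often enough that a barometer
fallback is required. Since the conversion is linear in $a$, altimeter
error propagates one-for-one into every length, and pixel digitisation
noise adds on top. Treating converted lengths as exact therefore
understates — and can bias — every downstream quantity, from body condition
to growth.

`aeromorph` treats the conversion as a hierarchical measurement-error
model: altitudes, instrument error parameters and true animal sizes are
estimated jointly, trained by flights over objects of known length.

## The hierarchical measurement-error model

For image $i$, altimeter $j$ (a drone may carry several), drone $d$, and
latent subject dimension $s$ (one total length or one width, pooled across
images according to the chosen grouping):

$$y_{ij} \sim \mathrm{N}\!\left(\beta_{0j} + \beta_{1j} a_i,\ \sigma_j^2\right),
\qquad
L_{p,m} \sim \mathrm{N}\!\left(\frac{L_s\, f_i\, I_{w,i}}{a_i\, S_{w,i}},\
\sigma_{px,d}^2\right).$$

The first line is the altimeter error model — additive bias, multiplicative
scaling, Gaussian noise per instrument. The second says the expected pixel
count is the true length divided by the GSD at the image's *true* altitude;
its variance is a per-drone pixel noise. Calibration measurements fix
$L_s$ at the known object length and so train
$(\beta_{0j}, \beta_{1j}, \sigma_j, \sigma_{px,d})$; animal measurements
leave $L_s$ latent. One latent altitude per image is shared by the
altimeter readings, the length and all widths measured on that image,
which is what carries the joint dependency of scale errors into every
posterior.

Grouping (`build_sampler(..., grouping =)`) sets the pooling of animal
measurements: `"image"` keeps one latent value per image (no pooling),
`"timepoint"` pools a subject's images within a day — the right scale for
widths and body condition — and `"subject"` pools everything, the right
scale for length in annual analyses. Pooling multiple images also absorbs
variation the model does not represent explicitly, such as an animal
sitting slightly below the surface in some images.

### Priors

| parameter | default prior | units | rationale |
|---|---|---|---|
| image altitude $a_i$ | log-Uniform(0.1, 130) | m | non-informative for a positive scale quantity; support wider than any legal flight |
| altimeter bias $\beta_{0j}$ | Normal(0, $10^2$) | m | launch-height mistakes and barometric drift are metre-scale; 10 m is generous |
| altimeter scaling $\beta_{1j}$ | Normal(1, $0.05^2$) | — | deliberately informative; see below |
| altimeter noise $\sigma_j$ | half-Normal(0, $10^2$) | m | covers barometers in poor conditions |
| pixel noise $\sigma_{px,d}$ | half-Normal(0, $20^2$) | px | covers sloppy digitisation at low resolution |
| object length $L_s$ | log-Uniform(0.01, 30) | m | calibration boards to blue whales |

Two of these defaults depart from the "make everything maximally diffuse"
habit, for a structural reason worth understanding before changing them.
The pixel likelihood constrains only the *ratio* $L_s / a_i$. The joint
posterior therefore contains a scale direction along which all latent
altitudes, all latent lengths, and $1/\beta_{1j}$ can move together with
almost no likelihood penalty, once many images carry latent lengths. Two
things pin that direction down:

* **The scaling prior.** Real altimeters do not mis-scale by 50%;
  barometers are within a few percent and LiDAR within ~1%. Normal(1,
  $0.05^2$) encodes that. With a diffuse scaling prior the scale direction
  is essentially unidentified and recovery of absolute sizes degrades
  badly in large multi-image datasets.
* **Flat-in-log latent priors.** Under flat-in-level priors on hundreds of
  altitudes and lengths, the posterior volume of the ridge's cross-section
  grows with overall scale (each latent's conditional width is relative,
  so it widens proportionally), which tilts the marginal posterior toward
  inflated sizes — the classic functional errors-in-variables pathology.
  The log-uniform (Jeffreys scale) prior contributes exactly the
  countervailing $-\log$ term per latent and cancels the effect. Flat
  `prior_uniform()` remains available for comparison.

An informative mode is the intended escalation path when calibration data
are thin: replace any of the defaults with tighter `prior_normal()` /
`prior_halfnormal()` choices grounded in instrument knowledge.
`prior_fixed()` pins a parameter entirely — fixing the altitude at the
observed reading and the pixel noise at a known value reduces the model to
a conjugate normal problem, which the test suite exploits as an exact
oracle.

### Sampler

The sampler is a component-wise Metropolis-within-Gibbs scheme written for
this model:

* latent altitudes: vectorised Gaussian random-walk Metropolis, one
  proposal scale per image, adapted in batches of 50 during burn-in toward
  0.44 acceptance and frozen afterwards;
* $(\beta_{0j}, \beta_{1j})$: exact bivariate-normal conjugate draws;
* $\sigma_j$, $\sigma_{px,d}$: log-scale random-walk Metropolis;
* latent lengths: exact truncated-normal conjugate draws (used as an
  independence proposal with a $1/L$ correction under the log-uniform
  prior);
* a joint *scaling move*: each connected component of the
  (image, latent length) measurement graph is proposed to scale by a
  common factor $\lambda = e^\varepsilon$. Pixel likelihoods are invariant
  along this direction, so acceptance is governed by the altimeter
  readings, any calibration measurements in the component, and the priors.
  Without this move the sampler is correct but crawls along the
  length–altitude ridge (effective sample sizes of tens rather than
  hundreds per 5,000 draws); with it, nominal 95% intervals attain their
  frequentist coverage in the package's replicate studies.

Determinism is part of the contract: `run_sampler()` seeds all randomness
from its single integer `seed` and identical calls return bit-identical
draws. Initial states come from the data (altitudes from corrected
readings, lengths from naively converted pixels); a non-finite initial
log-density aborts with a parameter report rather than sampling nonsense.
Retained draws are `(iterations - burn_in) / thinning` rows; effective
sample size (initial-positive-sequence estimator) and split-chain
$\widehat{R}$ are attached to every result.

Posterior summaries use the highest posterior density interval: the
shortest window of sorted draws containing the target mass, with ties
broken by the leftmost window. Degenerate (constant) draws give a
zero-width interval rather than an error.

## Body condition

`body_condition()` evaluates every metric on each retained draw, never on
posterior means, so nonlinearity propagates honestly — uncertainty visibly
grows with dimensional scale from standardized widths to projected area to
volume. Conventions, each chosen as the simplest defensible contract and
configurable:

* width stations at 5% increments of total length (labels `W5` … `W95`),
  matching common 20-segment practice;
* projected area by trapezoids between stations; volume by circular or
  elliptical frustums, where the elliptical volume is exactly the
  height-to-width ratio times the circular one (heights are not measured
  independently);
* the body is integrated between the first and last measured stations — no
  extrapolated head or fluke end caps;
* body area index: trapezoidal area of the region divided by the squared
  region length, region defaulting to (0.2, 0.7) of total length, reported
  as a raw ratio (a ×100 convention is a `scale` argument away);
* regions narrower than $10^{-3}$ of total length are rejected as
  degenerate rather than returning a meaningless ratio.

## Growth curves

`growth_curve_sampler()` embeds the same measurement model in a
hierarchical von Bertalanffy–Putter growth model:

$$L_{i,t} \sim \mathrm{N}\!\left(L_{\infty,i}\,
\bigl(1 - e^{-k(\mathrm{age}_{i,t} - t_0)}\bigr)^{b},\ \sigma_L^2\right),
\qquad L_{\infty,i} \sim \mathrm{N}(\mu_{\mathrm{sex}(i)}, \sigma_\infty^2),$$

with the expected length clamped at zero below $t_0$ and the Putter
exponent $b$ fixed at 1 by default (exposed as a configuration parameter).
Because $k > 0$, each individual's *expected* length is nondecreasing in
age in every posterior draw — the biological-realism constraint that keeps
repeated measurements of one whale coherent across years
(`check_growth_monotonicity()` verifies it at runtime). The growth prior
also shrinks noisy years toward the growth-consistent trajectory: an
individual measured by a barometer-only drone in one year and a
LiDAR-equipped drone in others gets a tighter posterior for the noisy year
than it would alone.

Design choices made where the design was genuinely open: the sex effect
acts on $L_\infty$ only (not on $k$); subjects of unknown sex form their
own group rather than being folded into either sex, and the effect is
disabled with a warning when no sex is known; interval ages get
independent uniform priors over their bounds (point ages are fixed) — a
deliberate simplification that ignores the deterministic year-to-year
increment of one individual's age; $t_0$ has a Normal(0, $2^2$) prior
truncated above at the earliest observed age; process noise $\sigma_L$ has
a half-Normal(0, 1 m$^2$) prior, wide enough for individual deviation
without swamping the curve. Updates for $L_{i,t}$, $L_{\infty,i}$ and
$\mu_{\mathrm{sex}}$ are conjugate; $k$, $t_0$, the variance parameters
and latent ages use adaptive Metropolis steps.

## Propagating uncertainty downstream

Two routes are supported and should agree. The *single-stage* route embeds
the downstream analysis in the joint model;
`single_stage_regression()` implements the linear-regression case with a
Gibbs sampler (latent predictors with their measurement posteriors as
priors). The *two-stage* route is multiple imputation
(`run_two_stage()`): draw completed datasets from the measurement
posteriors, run the primary analysis on each, perturb frequentist
estimates with multivariate-normal noise from their variance–covariance
matrix (Bayesian analyses contribute their own draws), and pool.

Choices worth knowing: imputations take *all* quantities of one dataset
from the same posterior draw index, preserving within-subject posterior
correlations (independent marginal sampling would understate correlated
uncertainty); indices are drawn without replacement up to the number of
retained draws; pooling is by simple concatenation of the perturbed
estimates, which approximates a posterior sample directly — a
Rubin's-rules summary is attached as an attribute for comparison, clearly
labelled, but is not the primary output; failing analysis callbacks are
skipped and counted, and more than 20% failures aborts the run rather
than silently reporting a biased pool.

## The synthetic-data generator

`simulate_calibration()`, `simulate_whales()` and
`simulate_growth_cohort()` generate tables with exactly the statistical
structure the model assumes — Gaussian altimeter errors around
$\beta_0 + \beta_1 a$, Gaussian pixel noise around the true pixel count,
uniform flight altitudes, a smooth parabolic-taper width template with
per-subject biological variation, and sex-specific von Bertalanffy growth
with process noise. Ground truth is returned alongside every table, and
all output is ingestible by `read_measurements()` unchanged.

Default study conditions: calibration flights of 20 images of a 1 m board
(the common field standard) at 10–60 m altitude — deliberately spanning
low passes, because the altimeter *intercept* is identified by
$1/n + \bar a^2 / S_{aa}$ and a flight that never goes low cannot pin it
down; a barometer with +2 m bias, unit scaling and 1 m noise; 5 px
measurement noise; and a two-drone contrast (LiDAR + barometer versus
barometer-only) mirroring common fleet upgrades. The growth cohort default
is 30 individuals followed for 7 years with two images per year, female
and male asymptotes of 12.5 and 11.9 m, $k = 0.25$, $t_0 = -1.8$ yr, and
0.3 m process noise — gray-whale-like values. Validation studies in the
test suite and acceptance script run at these sizes, with chains of
4,000–20,000 iterations (half burn-in); they complete on a single CPU in
minutes.

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify about real data: depth of the animal below the
surface (refraction changes the effective scale; the model only absorbs it
through multi-image variability), body-pose and image-quality effects
(quality enters only through the pre-filtering rules), analyst-to-analyst
digitisation differences, non-Gaussian or autocorrelated altimeter error,
and camera distortion beyond the scalar focal-length adjustment.

## Known limitations

* The altimeter intercept is weakly identified in small calibration sets:
  with 20 images and 1 m altimeter noise its posterior (and sampling)
  standard deviation is ~0.5 m even if altitudes were known exactly, so
  single-dataset bias estimates can sit 1 m from truth without any model
  failure. Fly more calibration images, and include low passes.
* Pixel noise shared per drone (configurable intent, one knob) rather than
  per label; very different digitisation difficulty between lengths and
  widths would violate it.
* No mass or energy conversion from volume (tissue density is out of
  scope), no lens-distortion field modelling, no photo-identification age
  estimation — ages or age bounds are inputs.
* Interval ages are independent across an individual's years; a shared
  birth-year parameterisation would be tighter.
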