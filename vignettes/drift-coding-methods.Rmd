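---
title: "Modelling retinal coding and acuity under fixational drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling retinal coding and acuity under fixational drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftcode)
```

## The scientific question

During steady fixation the eye drifts incessantly, sweeping the retinal
image over distances comparable to the spacing of foveal photoreceptors.
Whether this ocular drift helps or harms fine-detail vision is a
long-standing question: drift blurs a time-averaged image, but it also
refreshes receptive-field content and converts fine spatial structure
into temporal modulation of retinal spiking. `driftcode` implements a
complete computational account of this trade-off: a diffusion model of
drift, a spiking model of the foveal retinal ganglion cell (RGC) mosaic,
and a Bayesian ideal observer that reads orientation from the spikes in a
four-alternative forced-choice (4AFC) Snellen-E task.

## Drift as grid diffusion

Drift is modelled as a random walk on a square grid (spacing
`grid_spacing`, default 0.5 arcmin — the order of foveal cone spacing).
In each 50 ms bin the per-axis step, in grid units, is the difference of
two independent Poisson counts with means $\mu/2$; the step is therefore
symmetric, integer-valued, and has variance $\mu$. We parameterize by the
diffusion coefficient $D$ (arcmin$^2$/s), defined as the slope of the
*two-dimensional* mean square displacement versus time, so that

$$\mu = \frac{D\,\Delta t}{2\,s^2},$$

with $\Delta t = 0.05$ s and $s$ the grid spacing. One convention is used
everywhere: the generator (`generate_trajectory`), the decoder's
transition kernel (`make_transition_kernel`) and the estimator
(`estimate_D`, the mean of $(\Delta x^2 + \Delta y^2)/\tau$ at lag
$\tau = 50$ ms over all overlapping sample pairs) all satisfy
$\mathrm{MSD}_{2D}(t) = D\,t$. The Poisson-difference construction is our
choice among the integer-step processes with this variance; it has a
closed-form (Skellam) step pmf $P(k) = e^{-\mu} I_{|k|}(\mu)$, which
makes generator and kernel provably consistent.

Trajectories store *unwrapped* arcmin coordinates. The cyclic grid is a
computational device for the encoder and decoder state space, and the
wrap is applied only where positions index that grid; statistics such as
the MSD, the spectral slope or path length are computed on the true
displacements. `upsample_trajectory` linearly interpolates a trajectory
onto a ~960 Hz time base, emulating the effective sampling of a scanning
eye tracker, which is the time base on which spectra are reported.

The transition kernel is truncated at `kernel_radius` grid units per axis
and renormalized. Construction fails if truncation would discard more
than 1% of step mass; `kernel_radius_for(D)` returns the smallest
adequate radius, which the experiment drivers use so that large-$D$
conditions (e.g. $D = 200$) automatically get wider kernels. The default
radius of 4 is adequate up to $D \approx 25$ at the default spacing.

## Stimuli

`render_E` rasterizes a standard Snellen E on a 5 × 5 square of bar
units: bar thickness = gap width = `bar_size`, overall size
$5 \times$ `bar_size`, ink area $17\,\mathrm{bar}^2$. Stimulus size is
quoted both ways because the two scales differ by 5×; all APIs take
`bar_size` and report both. Rasters are anti-aliased by 8 × 8
supersampling per grid cell on an odd-sized pixel grid centred on the
letter, which makes the four orientations *exact* 90° rotations of one
another (the rectangles stay axis-aligned, and the sampling lattice is
rotation invariant). `apply_optical_blur` convolves with an isotropic
Gaussian of configurable FWHM (default 1 arcmin) as a stand-in for the
eye's point-spread function in natural viewing; the raster is padded so
total intensity is conserved exactly.

## The retinal model

Each of the $11 \times 11$ model RGCs (one per cone at the foveola) has a
circular Gaussian receptive field; centres sit on a jittered lattice
(jitter ±10% of spacing on positions and widths; the heterogeneous
variant triples the jitter to open coverage gaps). The rate of cell $i$
in bin $t$ is

$$r_i(t) = \max\!\Big(0,\; r_0 + \Delta r\,\big(O_i(t) - w\,O_i(t-1)\big)\Big),
\qquad \sigma_i(t) \sim \mathrm{Poisson}\!\big(r_i(t)\,\Delta t\big),$$

where $O_i(t)$ is the inner product of the unit-normalized receptive
field with the stimulus at its current grid position, $r_0 = 20$ Hz,
$\Delta r = 120$ Hz (values from foveal RGC electrophysiology), and
$w \in [0,1]$ weights a one-lag temporal kernel that makes responses
transient: with $w = 1$ a static stimulus drives spiking back to baseline
after one bin. Choices worth flagging:

* the Poisson mean is $r(t)\,\Delta t$ (rates stay in Hz; the bin width
  converts to counts);
* the linear rate is rectified at zero, since the temporal kernel can
  push it negative when a stimulus leaves a receptive field;
* $w$ defaults to 0.8 — the model constrains only $0 < w < 1$, and the
  qualitative behaviour (transient coding, drift-dependent accuracy) is
  insensitive to the exact value; `w = 0` is the unimodal-filter variant
  in which cells respond to intensity rather than intensity change;
* receptive-field width ($\sigma = 0.25$ arcmin) and mosaic density are
  not numerically pinned down by the source material; the defaults were
  chosen once so that discrimination becomes near-perfect for stimuli of
  about 2.5 arcmin overall and larger, and are not adjusted anywhere;
* the first bin's previous-frame overlap is 0: a blank screen precedes
  stimulus onset, in both the encoder and the decoder's likelihood;
* the overlap tables $O_i(\lambda, x, y)$ are computed once per
  configuration by FFT cross-correlation on the cyclic grid and shared by
  encoder and decoder.

## The ideal observer

The decoder maintains a joint posterior over orientation
$\lambda \in \{\text{up, down, left, right}\}$ and latent grid position,
updated recursively each bin by

$$P(\lambda, x, y \mid \sigma_{\le t}) = \frac{1}{Z_t}
\sum_{x', y'} \underbrace{P(\sigma_t \mid \lambda, x, y, x', y')}_{\text{likelihood}}
\; \underbrace{P(x, y \mid x', y')}_{\text{transition}}
\; \underbrace{P(\lambda, x', y' \mid \sigma_{\le t-1})}_{\text{prior}},$$

starting from a flat prior. The likelihood is the product of per-cell
Poisson pmfs; it depends on the *previous* position through the temporal
kernel, which is what forces the pairwise sum. The transition kernel is
the drift kernel above — the observer knows the drift statistics ($D$)
but never the trajectory. The decision is the argmax over $\lambda$ of
the position-marginal posterior (with a flat prior this coincides with
the likelihood argmax); exact ties are broken uniformly at random with
the trial's seeded RNG, which matters only in zero-information cases.

Numerics: the recursion runs in the log domain with per-position
max-shift; a rate floor of $10^{-6}$ Hz keeps log-likelihoods finite when
rectification yields a zero rate; cyclic index wrapping implements the
boundary conditions. Two implementations exist — a readable pure-R
reference (`update_posterior`) and a compiled path (`run_decoder`,
default) that precomputes, per configuration, the log-rate differences of
every (orientation, position, transition-offset, active-cell)
combination, reducing each bin to sparse dot products with the spike
vector. The suite asserts the two agree to machine precision, and that
both match exhaustive enumeration over all latent position paths on
small grids.

## Experiments and their scale

`run_condition` simulates full trials (random orientation → trajectory →
spikes → matched-model decoding) and `sweep_accuracy` crosses drift
amplitudes with stimulus sizes. Defaults are desk-scale: $D \in \{0, 25,
50, 100, 200\}$ arcmin$^2$/s × overall sizes 1.5–4 arcmin × 20 trials
per cell, with decisions recorded every 50 ms up to 500 ms. The
acceptance analyses use 400 zero-gain trials (chance level), 200
trajectories (spectral slope), $10^4$ bins (rate calibrations) and the
3 × 5 × 20 sweep; these sizes keep every analysis in the minutes range
on one core while leaving binomial/Monte-Carlo error well inside the
tolerances tested. Master seeds derive per-trial seeds through a
counter-based hash, so any single trial reproduces without re-running
its predecessors.

`make_subject_profiles` emulates the study population — 17 subjects × 2
eyes, per-eye base $D$ log-uniform on [30, 90] arcmin$^2$/s (≈3× spread),
36% of eyes with a linear size modulation of $D$ (total swing 50%, i.e.
drift amplitude growing with stimulus size, the direction implied by the
path-length analyses), 5% fit noise. These are defaults of an emulation,
not data, and conclusions drawn from them are about the model, not about
any subject. `stimulus_dependent_D_experiment` then compares accuracy
under empirical (per-eye, per-size), per-eye-averaged, shuffled, and
fixed $D$ values (profile quantiles plus 5× the maximum), quantizing $D$
to 10 arcmin$^2$/s by default so decoder tables are shared across eyes.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analyses assume:
isotropic diffusion, independent increments beyond one bin, $1/f^2$
position spectra, linear MSD, and a population spread of $D$. It omits
microsaccades, drift curvature or direction biases, tracker noise,
temporal correlations below 50 ms, and any dependence of drift on
retinal content. Tests passing on these data therefore validate the
pipeline's internal consistency and the model's qualitative claims
(chance at zero gain, evidence accumulation over time, an interior
optimum of accuracy versus $D$ for sub-receptive-field stimuli, near-
perfect decoding of large stimuli); they do not certify agreement with
any individual human observer, and the headline statistics of the human
dataset (e.g. a Kruskal–Wallis $H = 99$ across sizes) are emulated
qualitatively, not reproduced.

## Known limitations

* One temporal-kernel lag only; no ON/OFF pathways, centre–surround
  antagonism, adaptation, or correlated noise across cells.
* The decoder's grid discretizes position at cone spacing; sub-grid
  drift is invisible to both encoder and decoder.
* Rasterizing sub-pixel bars (bar sizes below the grid spacing) relies
  on anti-aliased coverage; bars below a quarter of the grid spacing are
  refused rather than rendered inaccurately.
* The optical blur stand-in is an isotropic Gaussian, not a measured
  human point-spread function.
* Decoder tables grow with kernel radius; very large $D$ (well beyond
  5× the empirical maximum) is computable but memory- and time-hungry.
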