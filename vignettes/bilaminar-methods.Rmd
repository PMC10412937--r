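---
title: "Decomposing and coupling bilateral laminar field potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing and coupling bilateral laminar field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilaminar)
```

## The problem and the model

Extracellular field potentials recorded along a linear probe spanning the
hippocampal CA1 and dentate gyrus are linear mixtures of the synaptic
currents of several afferent pathways, plus volume-conducted contributions
from remote structures. The package models the voltage at electrode $m$ as

$$u_m(t) = \sum_{n=1}^{N} V_{mn}\, s_n(t),$$

where the columns of $V$ are depth-loading profiles (one per field-potential
generator, i.e. per pathway) and $s_n(t)$ are the generator time courses.
ICA on the channels x time matrix estimates both factors blindly; the depth
profile identifies the pathway (a stratum-radiatum bump for the CA3-to-CA1
Schaffer input, a polarity reversal across the layer fold for the medial
perforant path, a flat profile for volume-conducted remote activity), and
the time course carries the pathway's activation free of contamination by
the others.

Everything downstream compares the left and right instances of each
generator: lagged cross-correlation, Welch coherence with a
phase-randomization surrogate threshold, windowed Pearson density
histograms at several time scales, temporal/spectral Granger causality with
block-resampling surrogates, and — for the pulse-like gamma waves of the
Schaffer generator — template deconvolution with bilateral pairing of
individual waves.

## Decomposition choices

**PCA pre-reduction and whitening.** The channel space is reduced to the
requested component count before ICA; this removes weak noise directions
and stabilizes convergence. The 1% relative-variance retention rule is
applied *after* the ICA, on reconstruction variance in the original channel
space.

**Contrast and restarts.** The ICA is a symmetric fixed-point iteration
with a logcosh (nonparametric negentropy proxy) contrast, restarted five
times from seeded random rotations; the best restart by summed negentropy
is kept. Kernel-density ICA is sometimes preferred for strongly rhythmic
laminar signals; recovery-based validation (see below) is
contrast-agnostic, and the logcosh fixed-point iteration is the field's
standard default, so the contrast is treated as a pluggable detail. Components are canonicalized —
unit-norm profile, largest-magnitude loading positive, variance-ordered —
so runs are comparable across hemispheres, epochs and seeds.

**Profile matching.** Left/right generator identification uses the
distance $1 - r$ (Pearson on loading vectors) with acceptance below 0.2 and
best-distance-first one-to-one resolution; an average-linkage tree over the
pooled profiles is attached for inspection. Pearson degenerates for exactly
flat profiles; such profiles never arise from real ICA output (estimates
fluctuate around flatness), and the ground-truth alignment helper uses the
uncentered (cosine) similarity instead, which remains defined.

**Epoch stability.** The bilateral correlation of a generator is computed
on epochs grown in 5 s steps; the reported minimal epoch length is the
smallest length from which the coefficient stays within 3% of the running
mean over shorter epochs. The step size is a package choice; the criterion
percentage is the standard one.

## Signal conditioning

Filtering applies the magnitude-squared response of a 4th-order Butterworth
filter in the frequency domain with mirror padding. This equals the
frequency response of a forward-backward (filtfilt) recursive
implementation — exactly zero phase, squared magnitude — while avoiding
recursive-filter edge transients; the passband is flat to well under 1% and
a tone one decade below the 0.5 Hz high-pass cutoff is attenuated by more
than 99.99%. Resampling is Fourier-domain (ideal anti-alias at the new
Nyquist); ratios that do not give an integral output length are rejected.
Faulty interior channels are replaced by the mean of their neighbours;
faulty edge channels are rejected outright. Large transients (sharp-wave
stand-ins) are masked by a robust threshold — median absolute deviation
times 1.4826, default 5 SD, 50 ms padding — and the returned mask is
honoured by the windowed and segment-based estimators.

## Surrogate-based significance

**Coherence.** Welch magnitude-squared coherence uses 1 s Hann segments
with 50% overlap (defaults; the estimator degenerates to 1 on a single
segment, so at least 8 segments are required). The null is built by
independently phase-randomizing *both* inputs — spectrum preserved to
machine precision, phases redrawn uniformly — and the per-frequency
threshold is the $k$-th order statistic of the surrogate coherences with
$k = \lceil (1-\alpha)(N+1) \rceil$. Under exchangeability this
construction has exactly level $\alpha$ at any surrogate count $N$; an
interpolated empirical quantile is biased at moderate $N$, inflating the
realized false-positive rate above the nominal level (the calibration
study in the test suite measures the realized rate directly). The default
count is 1000; the calibration studies in
the test suite and acceptance script run 400 surrogates per pair, purely
for runtime, since the order-statistic construction is count-exact. Results always report the
count used.

**Granger causality.** Pairwise temporal Granger statistics are
$F = \ln(\Sigma_{YY}/\Sigma'_{YY})$, the log residual-variance ratio of
own-past versus own-plus-other-past OLS autoregressions (order 12 at
250 Hz), computed per 5 s window at 80% overlap and averaged across
windows. Windows whose univariate reduced model is unstable (AR roots
inside the unit circle) are excluded from the average and counted. The
spectral statistic is the Geweke decomposition evaluated from the fitted
bivariate VAR transfer function — exact for the model class, with no
nonparametric spectral factorization. The surrogate null block-resamples
the putative source (single uniform cut, blocks swapped; a documented flag
resamples both inputs), recomputes the window-averaged statistic over the
same window set, fits a normal distribution to the surrogate values, and
thresholds at its 95th percentile. The fitted-normal threshold stabilizes
long before the default 1000 surrogates; the calibration studies use 100.
Stability screening is not repeated per surrogate: it would multiply the
cost roughly fifty-fold and only perturbs the null through the rare windows
whose stability status flips under resampling.

## Pulse deconvolution

Gamma waves are modelled as
$s(t) = \sum_k w_k f(t-\tau_k;\delta_k)$ with
$f(t;\delta) = H(t)\,(t/\delta^2)\,e^{-t^2/2\delta^2}$: unit area for any
$\delta$, peak $w\,e^{-1/2}/\delta$ at $\tau + \delta$. Fitting is greedy
penalized least squares: a matched filter over a log-spaced $\delta$ grid
(default 2–60 ms, 8 points) proposes the next event, L-BFGS-B refines
$(w, \tau, \delta)$ locally, and a final pass re-refines every event
against the residual. Two stopping rules: candidate peak below 4 robust
residual SDs (the principal detector), and residual-sum-of-squares
reduction below 0.5% of the signal power *per second* — the per-second
normalization keeps the rule invariant to record length, since a single
pulse's energy does not grow with duration while total power does. The
method presumes a stable baseline; when more than half the fluctuation
power lies below 4 Hz a quality warning is raised instead of trusting the
fit, which is the documented failure mode on dentate generators with
extensively overlapping gamma.

An event's support is $[\tau, \tau + 3\delta]$ (the template decays to
about 5.5% of peak there). Bilateral partners must overlap for at least
70% of the *shorter* support; admissible pairs are resolved to the exact
maximum-total-overlap one-to-one matching (branch-and-bound per connected
component of the candidate graph — components are tiny in practice), with
ties broken by the smaller onset difference. Amplitude covariation reports
Pearson r of paired absolute peak amplitudes, the orthogonal-regression
slope, and the RMS perpendicular distance to the identity line after each
side is normalized to its largest amplitude.

## The synthetic world

The generator emulates the standard six-generator scene: Schaffer (stable
baseline, negative-going ~36 Hz gamma pulses, sparse large SPW-like
events, strong bilateral gamma pairing), lacunosum-moleculare (slow
coherent waves), medial perforant path (polarity-reversing profile,
strongly coherent slow band), lateral perforant path (alpha-band bouts,
weakly coherent — the lateralized input), a granule-cell somatic generator
inheriting about half of LPP's events, and a flat volume-conducted remote
generator. Defaults: 32 channels at 65 um spacing per side, 60 s, 1 kHz,
variance shares 30/25/15/12/8/5% and sensor noise 0.04 mV — values chosen
once as a realistic irregular-activity regime; event rates are Poisson and
weights lognormal.

Three generative details deserve note:

* **Bilateral slow coupling** is a shared band-limited Gaussian component
  with per-side independent additions; with shared fraction $a^2$ of unit
  total variance the magnitude-squared coherence is $(a^2)^2$, so the gain
  solving a target $C$ is $a^2 = \sqrt{C}$. A target of exactly 1 is
  rejected as unconstructible alongside the independent per-side
  components.
* **Event inheritance** (the GCsom "noisy copy" of LPP) copies each parent
  event with probability 0.5, redraws its amplitude, and jitters its onset
  by 10 ms (synaptic transmission jitter). Zero-jitter copying was tried
  first and produced time courses correlated at −0.45 on the side carrying
  all mother events, which no ICA can separate — an unrealistic regime,
  given that the decomposition of real recordings does separate these two
  generators.
* **Relative variance is exact by construction**: time courses (and their
  event weights) are rescaled so each generator's share of the noiseless
  mixture variance equals its configured share, which makes the recovery
  benchmarks sharp.

What the generator does *not* emulate: biophysical volume conduction
(mixing is strictly linear with fixed profiles), theta states, ripple fine
structure, electrode drift, and non-stationary variance shares. A green
recovery test therefore establishes that the estimators invert the stated
linear model at realistic SNR — not that they are robust to everything real
tissue does.

## Numerical choices and degenerate inputs

Zero-variance inputs to correlation estimators raise errors (lagged CC) or
are recorded as missing (per-window Pearson). Gram matrices in the VAR
fits fall back to a 1e-10 ridge when singular; residual variances are
floored at machine epsilon, so the Granger statistic can touch but not
cross zero from below. ICA declares non-identifiability (a warning) when
every component's excess kurtosis is below 0.2 in magnitude. The
autocorrelation mean-frequency estimator interpolates its first
positive-lag peak parabolically and returns a flagged missing value when no
peak rises above 0.05. All stochastic entry points take explicit seeds;
the pipeline expands one global seed into fixed per-stage streams so
toggling one analysis never shifts another's randomness.

## Known limitations

* Per-shank ICA at 6 components on 60 s of 32-channel data takes a few
  seconds, but joint-bilateral mode doubles the channel count and is
  noticeably slower.
* The deconvolution is greedy; heavily overlapped events (separation well
  under one $\delta$) can merge, which is the regime the quality warning
  exists for.
* Spectral Granger uses the parametric VAR spectrum; narrowband structure
  far above the model order's resolution will blur.
* The flat remote generator's time course is Gaussian band-limited noise;
  its recovery by ICA rests on every other source being non-Gaussian (one
  Gaussian source is permitted), which the default scene satisfies.
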