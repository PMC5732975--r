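---
title: "Deconvolution, synthesis and statistics of 40 Hz steady-state responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution, synthesis and statistics of 40 Hz steady-state responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assrdeconv)
```

## The scientific problem

The 40 Hz auditory steady-state response (ASSR) is a quasi-sinusoidal EEG
response to rapid periodic auditory stimulation. One account of its
generation — the linear-superposition hypothesis — holds that the ASSR is
nothing more than the sum of overlapping transient auditory evoked
potentials (AEPs), one per click, shifted by the inter-stimulus interval
(ISI). Testing the hypothesis requires a template for the transient
response *at the steady-state rate*, which ordinary averaging cannot
provide because successive responses overlap. Two deconvolution strategies
make the template accessible:

* **CLAD** (continuous loop averaging deconvolution): a looped sweep of
  jittered ISIs whose averaged response is, under the superposition model,
  the *circular convolution* of the implicit transient response with the
  sweep's impulse train. The template is recovered by frequency-domain
  inverse filtering.
* **MSAD** (multi-rate steady-state average deconvolution): several
  isochronic sequences at different rates ("rate jitter" in place of ISI
  jitter). Each rate's one-cycle steady-state response is the transient
  folded at that rate's period; stacking the fold operators of all rates
  gives a linear system solved by SVD with optional regularization.

This package implements both paths, a synthetic-EEG generator that serves
as ground truth, the synthesis step (template → steady-state response), and
the comparison statistics: pointwise one-sample t-tests on difference
waveforms with a significant-fraction summary, and one-sample Hotelling
T² tests on six-element harmonic vectors (real and imaginary parts of the
first three stimulus-rate harmonics).

## The models

### Circular-convolution (jittered-sweep) model

With impulse train $s$ of length $N$ (one sweep) and implicit transient
$x$, the averaged sweep response is $y = s \circledast x$, so in the DFT
domain $Y(k) = S(k)X(k)$ and

$$\hat X(k) = \frac{Y(k)\,\overline{S(k)}}{|S(k)|^2 + \lambda}.$$

With $\lambda = 0$ this is exact division, valid when the sequence was
designed to keep $|S(k)|$ away from zero. The *noise gain*

$$C_{dec} = \sqrt{\operatorname{mean}_{k \in \text{band}}\,|S(k)|^{-2}}$$

summarizes how stationary noise passes through the inverse filter relative
to plain averaging; values below 1 mean the jittered paradigm is more
noise-efficient than averaging the same number of sweeps. The canonical
8-click sequence (ISIs 16.00, 28.80, 19.20, 27.20, 24.00, 32.00, 36.80,
20.80 ms; sweep 204.8 ms; nominal rate 39.0625 Hz, displayed as 39.1)
evaluates to `r round(noise_gain_cdec(to_impulse_train(make_clad_sequence(), 20000)), 4)`
under this package's band convention.

**Band convention.** `noise_gain_cdec()` averages over DFT bins whose
(folded) frequency lies in 10–1000 Hz — the recording passband — with DC
excluded. The value is invariant to the sampling rate because all in-band
bins coincide on any grid where the ISIs are integer samples. The
literature value for this sequence is 0.55; the defining reference's band
convention is not restated in the source we follow, and no simple band
reproduces 0.55 exactly (10–1000 Hz gives 0.564, 10–500 Hz gives 0.543).
The discrepancy (≈ 0.014) is documented here rather than hidden behind a
tuned band; the band is a user-visible argument.

### Fold-system (multi-rate) model

For period $P_r$ (samples) the one-cycle steady-state response is the fold
$b_r[n] = \sum_{m \equiv n \ (\mathrm{mod}\ P_r)} x[m]$, a binary matrix
acting on $x$. Stacking all rates gives $A x = b$ with
$\sum_r P_r$ rows. `msad_deconvolve()` solves this via the SVD either by
truncation (TSVD) or Tikhonov regularization
($\min \|Ax-b\|^2 + \lambda^2\|x\|^2$).

**Identifiability and the transient-support choice.** A natural choice is
to let the unknown $x$ span one full jittered sweep (204.8 ms), the same
support the circular model uses. That system, however, is *rank deficient*:
with the canonical eight periods the stacked fold matrix has rank 392 out
of 512 columns (at the 2.5 kHz grid; the proportion is the same at any
rate), so roughly the last quarter of the support is invisible to the data
and no regularizer can recover it. The pipeline therefore solves on a
configurable support, `msad_support_ms`, default **102.4 ms** — half the
sweep, comfortably longer than the click AEP (whose last component, Pb,
peaks near 52 ms), and well inside the full-column-rank region — and
zero-pads the estimate. With this support the noiseless solve returns the
truth to machine precision, which is what makes the end-to-end
superposition identity testable.

**Choosing the regularization strength.** `parameter = "auto"` uses
generalized cross-validation for Tikhonov and the discrepancy principle
(smallest truncation whose residual drops below
$\hat\sigma\sqrt{\text{rows}}$) for TSVD, with $\hat\sigma$ estimated from
the spectral coefficients in the last tenth of the singular spectrum when
not supplied. In the *pipeline* the default is `parameter = 0`: the
support-restricted system is well conditioned, and data-driven shrinkage
imposes a bias that is nearly identical across subjects. A shared bias
shifts the group-mean difference vector while leaving the between-subject
covariance untouched, which inflates the Hotelling type-I error — we
observed exactly this before changing the default. Regularization remains
available (and beneficial in RMSE terms, which the tests verify) for
ill-conditioned supports or very noisy observations.

## The synthetic world

`make_template()` builds the ground-truth transient AEP as a sum of
Gaussian lobes, one per canonical component:

| component | latency (ms) | amplitude (µV) | σ (ms) |
|---|---|---|---|
| V  | 7.05 | +0.44 | 0.8 |
| Na | 18   | −0.50 | 3 |
| Pa | 25   | +0.80 | 3.5 |
| Nb | 38   | −0.45 | 4 |
| Pb | 52   | +0.55 | 5 |

Wave V's latency and amplitude and Pa's ≈25 ms latency are the only
literature-anchored values; the remaining numbers are this package's own
choices of a plausible click AEP morphology and should not be quoted as
published values. Gaussians were chosen because peak latency and amplitude
are then exactly controllable — the sources we follow do not parameterize
waveshape. A configurable latency prolongation (`latency_shift_ms`,
suggested +0.5 ms) emulates the reported latency prolongation of
components recovered at 40 Hz stimulation.

Sweeps are simulated as the **circular** convolution of the impulse train
with the template plus band-limited Gaussian noise (white noise shaped by a
zero-phase 4th-order Butterworth-magnitude response over 10–1000 Hz, the
recording filter band, then rescaled to an exact per-sweep RMS; default
1 µV). The circular model means every simulated sweep is already in the
steady state: there are no onset/offset transients, so the
onset-discarding knobs in the preprocessing functions are inert on
synthetic data (a test asserts this). Occasional artifacts are injected as
single-sample 50 µV spikes — the simplest event a 40 µV rejection rule
must catch; rejection reads the rule strictly ("more than 40 µV"), so a
point at exactly 40 µV survives.

What a green test does **not** establish: the generator contains no
rate-dependent neural adaptation (unless planted via per-paradigm template
overrides), no inter-subject morphology variation, no drift, no non-
stationary noise, and no acoustic-delay effects. It validates the
*mathematics* of the pipeline — model inversion, synthesis, statistics —
not the physiology.

## Preprocessing conventions

* Averaging is the plain arithmetic mean.
* Data-quality score: Pearson correlation between odd- and even-indexed
  sweep averages; 0.5 is the suggested flagging threshold for
  simulated subjects (the underlying study excluded subjects for
  inconsistency without stating a numeric rule).
* The classical ("recorded") steady-state record is folded to one cycle
  and tiled to a four-cycle window: 102.4 ms at the 25.6 ms control ISI.
* The multi-rate record concatenates the per-rate one-cycle averages in
  the order of the jittered ISI list; its length is exactly one sweep.

## Statistics

* **Pointwise t-tests** on subject-wise difference waveforms, two-sided
  against zero, *no multiplicity correction* (deliberately, matching the
  procedure being emulated — the significant-fraction percentage is a
  descriptive summary, not a corrected inference). Zero-variance samples
  get `p = 1` if the mean is zero, else `p = 0`.
* **Harmonics**: coefficients at DFT bins $C, 2C, 3C$ of a $C$-cycle
  record, scaled so a cosine of peak amplitude $A$ has magnitude
  $A/\sqrt2$ (RMS convention).
* **Hotelling T²**: $T^2 = n\,\bar x' S^{-1} \bar x$,
  $F = T^2(n-p)/(p(n-1)) \sim F(p, n-p)$. The confidence ellipsoid scales
  eigenvectors of $S/n$ by $\sqrt{\frac{p(n-1)}{n-p}F_{1-\alpha}(p,n-p)}$.
* **Outlier screen** (stand-in for a normality-macro-driven removal whose
  criterion is unavailable): robust Mahalanobis distances from a minimum
  covariance determinant fit, with the standard consistency correction and
  iterated reweighting, flagged beyond the χ²(p) 97.5 % quantile. Because
  the substitute differs from the original procedure, specific excluded-
  subject indices are not reproducible and are not claimed.

## Numerical choices and degenerate inputs

* All ISIs must be integer sample counts at the working rate; the
  canonical ISIs are multiples of 0.4 ms, so any multiple of 2.5 kHz
  works. Tests run at 2.5 kHz (sweep = 512 samples, exact arithmetic);
  the simulation default is the 20 kHz recording rate.
* Inverse filtering refuses in-band spectrum magnitudes below `1e-8`
  without a ridge, and refuses outputs whose imaginary residue exceeds
  `1e-9` of the signal RMS (a violated-model detector).
* 0-based sample indexing for stimulus onsets; the first click sits at
  index 0; sweep boundaries are circular ("continuous loop").
* Rates are reported to one decimal (39.1 Hz) while internal values stay
  exact (39.0625 Hz).
* Component isolation zeroes outside hard windows by default (an optional
  1 ms cosine taper is off by default, matching the hard "zeroing"
  description of the emulated procedure); the baseline is the mean over
  0–1 ms pre-stimulus. Default windows — V [5, 12], Na [12, 22],
  Pa [22, 35], Nb [35, 48], Pb [48, 70] ms — are conventional choices,
  anchored only by the V and Pa latencies.
* Degenerate Hotelling inputs (differences at numerical-dust level,
  `max |v| < 1e-9` µV) are reported as absent tests rather than
  singular-covariance errors.

## Design decisions that were genuinely open

* **MSAD support** (above): identifiability forced a departure from
  "support = full sweep".
* **Pipeline regularization default 0** (above): group-level calibration
  beats per-subject RMSE once inference is the goal.
* **C_dec band**: 10–1000 Hz documented default; no claim to reproduce the
  0.55 literature value exactly.
* **Per-rate sweep length**: multi-rate sweeps cover
  `ceiling(support / period)` cycles so a single sweep spans the template;
  the control sweep likewise covers at least the template support before
  folding. With circular simulation the cycle count only affects noise
  averaging, not the signal.
* **How many cycles feed the one-cycle average** is a free knob
  (`discard_cycles`), as the emulated procedure does not state it; on
  circularly simulated data it is provably inert.

## Limitations

* The synthetic world is linear by construction: it can *refute* a broken
  pipeline but cannot provide evidence about real neural superposition.
* The reported 45.95 / 36.28 / 10.84 % significant fractions and the
  contribution table of the underlying study derive from human recordings
  that were never deposited; the package reproduces the *procedures* and
  verifies them on synthetic ground truth instead. Published values that
  are reproducible from printed inputs alone (sequence metrics, the three
  T²→F conversions) are reproduced exactly.
* `fold_svd()` uses a dense SVD — fine up to the 4096-sample sweeps of the
  20 kHz grid, by design; no iterative solver is provided.
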