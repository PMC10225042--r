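---
title: "Acoustic analysis of airway-protective maneuvers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic analysis of airway-protective maneuvers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tussilab)
```

## The problem

Voluntary coughs, voluntary throat clearings, and induced reflexive coughs
are airway-protective maneuvers whose efficacy matters clinically — for
example in assessing aspiration risk in dysphagia. They are transient
acoustic events (on the order of 0.3–0.5 s) that evolve rapidly and
incessantly, which makes spectrogram-style analysis (designed for
quasi-stationary sounds) a poor fit. `tussilab` implements an alternative:
a small set of temporal and spectral features computed on the whole
maneuver, robust enough to compare maneuver classes with nonparametric
statistics.

This vignette describes the model and procedure, every tunable that
matters, the synthetic-data generator used to validate the pipeline, and
the numerical choices and known limitations.

## Segmentation

Recordings are assumed pre-split to a single maneuver flanked by silence
(the initial by-hand split of multi-maneuver bouts is out of scope). The
maneuver's acoustic extent is then found automatically from the energy
envelope:

1. `envelope_contour()` computes per-frame mean-square levels in dB
   relative to the loudest frame (frame 10 ms, non-overlapping by default;
   a final partial frame is kept with its true length so a drawn-out offset
   is never dropped).
2. `auto_trim()` takes the onset as the start of the *first* frame, and the
   offset as the end of the *last* frame, whose level is **strictly greater
   than −30 dB** relative to the envelope maximum. A frame at exactly
   −30.000 dB is excluded. Boundaries are frame-aligned, 0-based, half-open.
3. `normalize_energy()` divides the trimmed segment by its RMS so the
   average signal energy equals one. This removes pre-amplifier gain and
   microphone-placement effects from all downstream features; absolute
   intensity is deliberately *not* recoverable from the signal (it would be
   measured with a sound-level meter).

How the envelope for the −30 dB rule should be computed is genuinely open;
we chose the simplest contour consistent with a frame-wise threshold rule
(per-frame mean-square level, 10 ms, hop = frame) and made frame and hop
configurable. Trimming is scale-invariant and idempotent: re-trimming a
trimmed, normalized segment returns it unchanged.

## Temporal contours and DCT shape descriptors

Three per-frame statistics are tracked over the segment (default frame
20 ms, hop 10 ms — chosen so a 0.3 s maneuver yields ≈ 30 frames, enough to
support three DCT coefficients):

* **Amplitude** — per-frame mean energy (mean squared sample). We use mean
  energy rather than peak or RMS because, under energy normalization and
  tiling frames, the duration-weighted contour average is then *exactly*
  one, making the contour a pure shape descriptor of relative strength.
* **Sample entropy** — `SampEn(m, r)` per frame: the negative log of the
  conditional probability that template matches of length `m` persist at
  length `m + 1` (Chebyshev distance, self-matches excluded). High for
  turbulence noise, low for locally periodic oscillation. Defaults are the
  canonical `m = 2`, `r = 0.2 ×` frame SD. Each frame is first
  coarse-grained by block means to ≤ 4410 Hz; this bounds the quadratic
  template search (a 20 ms frame at 44.1 kHz becomes ~88 points) and is the
  multiscale-entropy convention for rate reduction. Frames where either
  match count is zero are *undefined*; a constant frame is perfectly
  predictable and scores 0.
* **Kurtosis** — Pearson (non-excess) `m4 / m2²` with `1/n` moments: 3 for
  Gaussian frames, 1.5 for a sinusoid, large for burst-like onsets.
  Zero-variance frames are undefined. (We anchor only the Gaussian ↦ 3
  case; the common claim that uniform histograms give kurtosis near zero
  conflicts with the standard value 1.8 and is not encoded anywhere.)

Each contour is summarized by its first three type-II DCT coefficients with
a length-comparable scaling (`c0` as the plain mean; `c1`, `c2` scaled by
`2/N`): **average**, **slope**, and **curvature**. Signs follow the
co-sinusoidal basis: a *positive slope* coefficient means a contour
*decreasing* with time; a *positive curvature* means a downward–upward
(convex) contour, negative means upward–downward (concave). Undefined
frames are dropped before the fit rather than imputed — we prefer a
slightly shorter contour to fabricated values. At least three defined
frames are required.

```{r}
g <- generate_maneuver(maneuver_spec("voluntary_cough", seed = 1))
seg <- trim_segment(g$waveform)
contour_shape(amplitude_contour(seg))
```

## Spectral decomposition

`dct_band_decompose()` computes one orthonormal type-II DCT over the whole
segment (the maneuver is analyzed as a single transient, not per frame),
assigns coefficient `k` to the band containing its frequency
`f_k = k · rate / (2N)`, and reconstructs per-band constituent signals by
inverse DCT. Band edges are 400, 800, 1600, 3200 Hz, and Nyquist; a
coefficient exactly on an edge goes to the higher band. Because the DCT's
implicit even extension pivots the signal at onset and offset, no artificial
discontinuity between the drawn-out offset and the abrupt onset enters the
spectrum, and the decomposition is *exact*: constituents sum to the segment
and their energies sum to the segment energy (Parseval), both to
floating-point precision.

The typical frequency of each band is estimated by *unidirectional* zero
crossings — upward (negative → non-negative) transitions per second, which
counts `f` crossings per second for a sinusoid at `f` Hz; zero samples are
treated as non-negative, and a crossing-free constituent reports 0 Hz with
zero weight. The **weighted frequency** — band frequencies weighted by
relative band energies and summed — approximates the spectral centroid.

## The synthetic maneuver generator

Real recordings of these maneuvers are not publicly distributable, so the
pipeline is validated end-to-end on synthetic waveforms that emulate the
qualitative acoustic structure of each class:

* **voluntary cough** (default 0.39 s): burst-like onset — broadband noise
  under a sharply decaying envelope with a sub-800 Hz oscillation —
  followed by decaying frication (400–2500 Hz) and, with probability 0.5, a
  voiced coda; the amplitude contour is high at onset, decays, and may
  re-rise, hence convex.
* **throat clearing** (0.46 s): weak onset and one sustained 100–300 Hz
  amplitude-modulated oscillatory fragment whose envelope rises and falls,
  hence a concave amplitude contour and energy concentrated below 800 Hz.
* **reflexive cough** (0.31 s): a 5–15 ms high-gain pulse followed by
  frication extending 800–9000 Hz, hence the highest onset kurtosis and
  more high-band energy than a voluntary cough.

Default durations target the typical class medians. Noise fragments are
Gaussian white noise band-shaped by the same DCT filter bank used for
analysis. Cohorts draw lognormal subject random effects (σ = 0.15) for gain
and duration once per subject, with σ = 0.05 token jitter, so durations are
correlated within subject; all randomness is Mersenne-Twister under a
single master seed and every token's waveform is bit-reproducible. The
skin-contact channel model is a zero-phase order-6 Butterworth low-pass at
1.5 kHz (well over 40 dB stop-band an octave up), emulating the attenuation
of high frequencies propagating through neck tissue; it lowers the weighted
frequency of any broadband maneuver, as a tissue-borne channel should.

What the generator does **not** emulate: vocal-tract resonances, glottal
source physiology, room acoustics, inter-token airflow dependence, or any
dose–response of cough induction. Passing end-to-end checks therefore
validates the *pipeline's wiring and statistics*, not biological claims.

## Statistics

Features are compared at the token level: medians, quartiles, minima,
maxima, and a percentile bootstrap 95% CI of the median (B = 2000,
resampling tokens; the quartile convention is linear interpolation,
type 7). Paired contrasts (same subjects and token indices in both groups)
use the Wilcoxon signed-rank test: zero differences dropped, ties
midranked, exact two-sided p by full enumeration of sign assignments for
n ≤ 25 (computed by a generating-function convolution, valid under ties),
otherwise a tie- and continuity-corrected normal approximation.
Independent contrasts use the Mann–Whitney U test
(`U = Σ [xᵢ > yⱼ] + ½[xᵢ = yⱼ]`), exact by enumeration of labelings for
n₁ + n₂ ≤ 20 without ties, approximate otherwise. Raw p-values are flagged
at α = 0.05 with no multiplicity correction.

A caveat we inherit deliberately: testing at token level ignores
within-subject clustering. With several correlated tokens per subject the
nominal test size is inflated — in the synthetic null contrast
(urge-to-cough vs suppressed labels with identical generator parameters)
most runs show ≥ 90% of features non-significant, but some seeds fall
below that. Mixed-effects or cluster-robust inference would fix this and is
explicitly out of scope; the package mirrors the token-level convention and
documents the caveat instead.

## Numerical choices and degenerate inputs

* DCT-II/DCT-III are computed via the FFT of the even extension; exactness
  is asserted in tests to 1e-9 relative L2 (observed ~1e-13).
* All-zero waveforms cannot be trimmed (error: "no acoustic content");
  zero-energy slices cannot be normalized.
* Frame-level undefined values (zero-variance kurtosis frames, matchless
  entropy frames) are carried as `NA`, logged by the pipeline per file, and
  dropped before shape fitting.
* Degenerate features in a contrast (all paired differences zero) are
  reported with p = 1 rather than aborting a whole run.
* Integer WAV samples are scaled by `2^(bits−1)` (asymmetric full scale);
  float WAVs round-trip bit-exact at 64-bit. Rates other than 44.1 kHz are
  accepted and propagated — no resampling is performed, since all features
  are defined per second or per frame.

## Problem sizes used in validation

The test suite and the acceptance script validate: the Gaussian kurtosis
anchor on 10⁶ samples; filter-bank exactness on 1000 random segments of
64–4096 samples; sample entropy against a brute-force O(n²) oracle on 100
frames of ≤ 300 samples; rank tests against exhaustive enumeration at n = 8
(2⁸ sign patterns) and 6 vs 6 (all C(12,6) labelings) plus 1000-replicate
null-size simulations; and an end-to-end cohort of 40 subjects × 5 tokens ×
3 classes (600 maneuvers) for the class-direction checks. These sizes keep
a full validation run in the low minutes on one core while leaving the
statistical margins wide.

## Known limitations

* Signal amplitude reports relative strength only; intensity in dB SPL is
  not modeled (it would come from an external meter).
* The envelope used for trimming is a declared choice, not an identified
  convention; results near the −30 dB boundary can move by one frame under
  a different envelope.
* Sample-entropy values depend on `m`, `r`, and the coarse-graining rate;
  only comparisons under a fixed configuration are meaningful.
* Token-level inference under clustering, as discussed above.
* The synthetic generator supports pipeline validation, not acoustic
  realism; effect directions it reproduces are built into its construction.
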