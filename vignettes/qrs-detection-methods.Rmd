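---
title: "Methods: exponential-transform QRS detection with a PD-controlled threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exponential-transform QRS detection with a PD-controlled threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etqrs)
```

## The detection problem

A QRS-complex is the dominant deflection of the electrocardiogram; locating
its apex (the R peak) is the first step of essentially all automatic ECG
analysis.  The difficulty is variability: QRS morphology changes across
subjects and over time, ectopic beats (PVCs) are wide and low-amplitude,
tall T waves imitate QRS deflections, and the signal carries baseline
wander, powerline interference and muscle noise.  `etqrs` implements a
five-stage streaming detector built around two ideas: a nonlinear
*exponential transform* that narrows the height gap between large and small
QRS peaks, and an adaptive threshold driven by a *proportional-derivative
(PD) control* recursion toward a fixed floor.

## The pipeline

**1. Band-pass filter.** A 41-tap linear-phase FIR filter (Hamming
windowed-sinc, passband 5–15 Hz) enhances the QRS band.  Being symmetric,
it delays every component by exactly $(41-1)/2 = 20$ samples; the pipeline
subtracts this delay when reporting beat positions.  A caveat worth stating
plainly: at 360 Hz, 41 taps give a transition band (~35 Hz) far wider than
the 5 Hz lower edge, so the filter alone attenuates DC only to a gain of
about 0.79.  The strong low-frequency rejection of the pipeline comes from
the next stage.

**2. First difference.** $d(n) = f(n+1) - f(n)$ has gain
$2\sin(\pi f/f_s)$, i.e. about 0.005 at 0.3 Hz — this is what removes
baseline wander and the slow P/T deflections while keeping the steep QRS
slopes.

**3. Exponential transform and accumulation.**
$e(n) = |d(n)|\,e^{-|d(n)|}$ rectifies both polarities and compresses large
slopes (the compression ratio grows with $|d|$), equalising QRS peak
heights so one threshold can serve large and small beats.  A first-order
Taylor variant $|d| - d^2$ is provided for hardware-parity studies; it is
clamped at zero where $|d| > 1$ would make it negative (the exact transform
is non-negative by construction), and agrees with the exact form to
$O(|d|^3)$.  The feature signal
$s(n) = \sum_{i=n-\lfloor q/2\rfloor}^{n+\lfloor q/2\rfloor} e(i)$
accumulates $e$ over one nominal QRS duration
($q = \lfloor 0.120\,f_s \rfloor$, 43 samples at 360 Hz).

**4. Extreme points and PD threshold.** The filtered signal is scanned in
consecutive windows of $\lfloor 0.260\,f_s\rfloor = 93$ samples (about one
beat at the fastest plausible rate), each extended by
$\lfloor q/2\rfloor = 21$ context points so edge extremes are not missed.
A point is an extreme iff $(f(n)-f(n+j))(f(n)-f(n-j)) > 0$ for every
$j = 1..21$ — ties fail the strict inequality.  The per-window threshold
follows

$$TH[w] = TH[w-1] - a\,(TH[w-1] - TH_{\min}) - b\,\Delta TH$$

with $a = 0.5$, $b = 0.1$, $TH_{\min} = 0.15$, interpolated linearly inside
the window.  An extreme qualifies when the maximum of $s$ within ±15
samples of it (absorbing the differencing/accumulation delay) exceeds
$M = 1.5$ times its interpolated threshold; the largest-$s$ qualifier wins
the window, and a detection overwrites the window's threshold with the
detected $s$ value.  With no detections the threshold decays geometrically
to the floor: from a threshold of 1 it is within 0.01 of $TH_{\min}$ in
under 20 windows, and it provably never drops below the floor (each update
is a convex combination of previous thresholds and $TH_{\min}$).

**5. Refractory and tall-T rejection.** Candidates of successive windows
closer than one window length (260 ms) are duplicates or noise: the
larger-$s$ one survives and the loser's threshold registration is rolled
back by replaying the recursion from the state at its window entry.
Separately, when two kept candidates are closer than $\overline{RR}/K$
(running mean RR, $K = 3$), they are taken to be the QRS and the tall T
wave of one beat and the larger-$s$ one is kept.

## Design choices where the design was open

* **Recursion form.** The published recursion and its pseudocode disagree
  on the derivative term's lag (adjacent windows vs. two windows back).
  The pseudocode — the form that was actually implemented in the reference
  hardware — is taken as normative: the update is
  `TH3 <- TH3 - a(TH3 - TH_min) - b(TH3 - TH1)` followed by the role shift.
  Both variants share the floor, the fixed point and the convergence rate
  to within a few times $10^{-7}$.
* **Threshold initialisation** is not published.  `init_state()` starts the
  recursion at $\max(TH_{\min},\ 0.5 \times \max s)$ over the first 2 s, so
  the first true beat (whose $s$ is near that maximum) still clears the
  $M = 1.5$ multiplier while startup noise does not.  Both the scale and
  the startup span are configurable.
* **Tall-T comparison direction.** Read literally, the published rule fires
  when the interval is *larger* than $\overline{RR}/K$ — which would reject
  one beat of nearly every normal pair ($\overline{RR} > \overline{RR}/3$
  always).  The stated purpose (rejecting the second candidate of the same
  beat) forces the opposite direction, which is the default; the literal
  direction is preserved behind `tall_t_literal = TRUE` for comparison.
* **Candidate anchoring.** The band-pass turns each QRS into a short
  wavelet whose side lobes are extremes too, and adjacent extremes often
  share the same ±15-sample search maximum.  Exact-$s$ ties are therefore
  broken toward the extreme with the largest filtered amplitude — the
  apex — both inside a window and across the refractory comparison.
  Without this, reported positions could sit a side lobe (~40 ms) early.
* **Windows tile; they do not slide point-by-point.**  The per-window
  threshold recursion ($TH[w]$, $TH[w-1]$, $TH[w-2]$) only makes sense for
  a discrete window sequence, so "sliding" means advancing by one window
  length.
* **Units.** Millivolts are the canonical amplitude scale; $TH_{\min} =
  0.15$ is interpreted in feature-signal units on mV-scale input.  Note the
  published constants' absolute scale is not fully documented; on mV-scale
  input, typical $|d|$ is ~0.1, where the exponential compression is mild.
  A 10× rescale of the input changes the detection count by under 1% on
  clean synthetic data because initialisation is data-driven; the fixed
  floor is the residual scale sensitivity.

## Streaming and chunking

Every stage is causal with bounded look-ahead (the accumulation needs
$\lfloor q/2\rfloor$ future samples, the screening ±15), so the engine
processes a window only when its right margin is available and defers the
rest to the next chunk.  Because the FIR is applied by direct (non-FFT)
convolution, per-sample results are bit-identical however the record is
chunked: `chunk_state = "persist"` therefore reproduces the whole-record
result exactly, not just away from seams.  `chunk_state = "reset"`
re-initialises thresholds and the RR tracker every `chunk_samples`
($2^{14}$ by default, ~45 s at 360 Hz), emulating evaluation on independent
analysis units; a cross-seam refractory sweep keeps the spacing invariant.

## The synthetic world, and what a green test does not establish

The generator places Gaussian bumps (P, Q, R, S, T) at log-normally
distributed RR intervals — defaults: 72 bpm, RR coefficient of variation
0.05, R amplitude 1 mV with 5% beat-to-beat variation; per-wave amplitude,
width (Gaussian $\sigma$, in ms) and offset from the R centre are fixture
constants, not physiological claims.  PVC-like beats replace the R bump
with a 0.45 mV, 60 ms bump and drop the P wave; tall-T beats raise the T
amplitude to 0.85× the beat's R; white noise is added last at a configured
SNR (realized within 0.5 dB), plus optional sinusoidal baseline wander
(< 0.5 Hz) and powerline interference.  Ground truth is the exact R-centre
sample of every placed beat.

What this emulates well: quasi-periodicity, rate changes, amplitude
variation, the small/wide-beat challenge, additive noise.  What it does not:
real QRS morphology (no notching, no axis shifts), non-stationary noise
bursts, electrode artefacts, rhythm pathologies such as flutter or
fibrillation.  A green synthetic test therefore establishes algorithmic
correctness of the pipeline, not clinical-grade performance; the optional
`scripts/validate_mitdb.R` exists for evaluation on real data.

One stated-world limitation deserves emphasis.  With the default template,
the tall-T fixture cannot demonstrate the rejection stage end-to-end: a
$\sigma = 70$ ms Gaussian T is too smooth to produce a candidate at all
after filtering and differencing, and even a sharpened T at the template's
+300 ms offset cannot be rejected, because the cutoff at 72 bpm is
$\overline{RR}/3 \approx 278$ ms < 300 ms.  The stage is therefore
exercised in the test suite on a hand-built record (RR 1100 ms, sharp
0.85 mV T on a minority of beats), where it removes every T false positive
at no sensitivity cost, and the preset-based end-to-end assertion is left
failing by design rather than silently weakened.  Relatedly, the running
mean RR self-pollutes once T false positives are *accepted* (each splits
one RR into two short intervals, shrinking the cutoff further), so the
stage degrades gracefully rather than recovering late — a property of the
published rule, not of this implementation.

## Numerical choices

* Strict inequalities throughout (`>` in the extreme criterion and the
  threshold test): plateau ties are not extremes.
* Sample-count parameters derive from their ms definitions by `floor`
  (window 93, accumulation 43 at 360 Hz); the search radius scales as
  `round(15 fs/360)`.
* Metric display rounds half-up to 2 decimals; raw ratios are retained.
  Zero denominators yield `NA`, not errors.
* Beat matching is greedy nearest-within-tolerance, one-to-one, in
  ascending time; enlarging the tolerance never decreases TP.  The default
  300 ms tolerance follows the reference evaluation protocol and is
  unusually wide; 150 ms is conventional and configurable.
* All public beat indices are 0-based sample positions (matching the
  on-disk formats); intervals are half-open.
* Degenerate inputs: records shorter than one window error cleanly;
  all-zero records initialise the threshold at the floor and report zero
  beats; positions that would precede the record after delay compensation
  are clipped to 0 with a warning, and beats inside the initial filter
  transient are suppressed.
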