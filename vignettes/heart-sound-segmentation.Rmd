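---
title: "Shannon-energy heart sound segmentation: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shannon-energy heart sound segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartseg)
```

## The problem and the model

A phonocardiogram records the pressure sounds of the closing heart
valves: S1 (mitral/tricuspid closure, start of systole) and S2
(aortic/pulmonic closure, start of diastole). Segmenting S1 and S2 is the
first step of most automated auscultation pipelines, and it is hardest in
pediatric recordings — faster rates, larger beat-to-beat variability, and
frequent high-energy artifacts from crying or stethoscope motion.

The segmenter works on the *average Shannon energy* (ASE) envelope.
Shannon energy, $-x^2\log x^2$, emphasizes medium-intensity components
while suppressing both low-level noise and extreme peaks, which suits
heart sounds well. The pipeline is:

1. **Preprocess.** Resample to 4 kHz, bandpass 40–500 Hz, normalize to
   $[-1,1]$. Heart sound energy lies almost entirely in this band.
2. **Envelope.** ASE over 20 ms windows with 50 % overlap; the
   *normalized* ASE (NASE) subtracts the envelope mean, so thresholding
   at 0 marks where the signal is more energetic than its own average.
   Candidate *lobes* are maximal supra-threshold runs.
3. **Validate.** Physiological priors: primary sounds are shorter than
   250 ms; physiological splitting of S1/S2 produces two sub-lobes less
   than 50 ms apart with clearly unequal intensity (we use RMS ratio
   below 40 %), in which case only the stronger lobe is a candidate.
4. **Identify.** The diastolic interval (S2→S1) is normally longer than
   the systolic interval (S1→S2) and the systole is the stabler of the
   two. The pair of lobes bounding the longest onset-to-onset interval
   therefore anchors the chain as (S2, S1); extension proceeds forward
   and backward, scoring candidate pairs by envelope correlation with
   the previously accepted systolic stretch plus deviations from running
   cycle and systole estimates.
5. **Noise robustness.** Artifact lobes carry far more envelope area
   than heart sound lobes. Their areas are screened with a population
   z-score and cutoff 2.75; flagged lobes are cropped with a small
   margin, and each remaining clean interval is segmented independently
   with the envelope recomputed per interval.

## Tunable parameters

All thresholds live in `seg_params()`:

| parameter | default | unit | role |
|---|---|---|---|
| `max_sound_ms` | 250 | ms | maximum S1/S2 lobe duration |
| `max_split_ms` | 50 | ms | maximum split-sound gap |
| `split_rms_ratio` | 0.40 | – | split-sound intensity asymmetry |
| `area_cutoff` | 2.75 | – | z-score cutoff for outlier lobes |
| `corr_weight`, `cycle_weight`, `sys_weight` | 1/3 each | – | pair-score mixture |
| `min_pair_score` | 0.5 | – | chain-extension acceptance floor |
| `frame_len_s`, `overlap` | 0.020 s, 0.5 | – | envelope windows |
| `crop_margin_s` | 0.050 | s | guard band around cropped lobes |
| `min_clean_s` | 2.0 | s | shortest clean interval worth segmenting |
| `cycle_window` | [0.5, 1.5] | ×cycle | next-S1 search window |
| `sys_window` | [0.3, 2.0] | ×systole | candidate-systole plausibility |

The first four and the envelope windows come from the published method;
the rest are this package's own choices where the method is silent. The
equal pair-score weights reflect that the three measurements are named
but not weighted in the source method; `min_pair_score = 0.5` demands
more evidence than the cycle/systole terms alone can provide only when
correlation is informative. The crop margin of 50 ms reuses the split-
interval scale as a guard against burst tails; `min_clean_s = 2` s admits
at least one full cycle even at low pediatric rates (a 40 bpm cycle is
1.5 s). The candidate windows bracket physiological beat-to-beat
variability generously.

A *success* flag additionally requires the final cycle estimate to lie
in the physiological 40–220 bpm range. Without this bound, unstructured
broadband noise — whose dense, weakly correlated lobes can chain by
chance at implausibly short "cycles" — would occasionally be reported as
a successful segmentation.

## Design choices in detail

**Shannon energy form.** The envelope is
$E_s = -(1/N)\sum x^2 \log x^2$ with natural log and $0\log 0 := 0$ —
the standard average-Shannon-energy form used throughout the PCG
envelope literature. The choice of logarithm base only rescales the ASE
and cannot change NASE thresholding; it is fixed for test determinism.
The form is isolated in one internal function (`shannon_energy`) for
auditability.

**Frame-to-time mapping.** A lobe spanning frames $k\ldots m$ (0-based,
hop $h$ = 10 ms, window $w$ = 20 ms) maps to $[kh,\; mh + w)$ — the full
extent of every contributing window. Intervals are half-open seconds
everywhere; sample indices are 0-based.

**Filters.** The bandpass is realized as a cascade of 4th-order
Butterworth highpass (40 Hz) and lowpass (500 Hz) sections, each applied
forward-backward (zero phase, so sound onsets are not delayed).
A cascade was chosen over a single bandpass design because "4th-order
bandpass" is ambiguous (prototype vs realized order) and the cascade is
numerically better conditioned at a 4 kHz rate. Resampling is done in
the Fourier domain (spectrum truncation/zero-padding), which applies an
ideal anti-alias filter implicitly and yields exactly
$\mathrm{round}(n \cdot 4000/f_s)$ samples; no polyphase primitive
exists in the installed R stack, and at these signal lengths the
$O(n\log n)$ transform is not a bottleneck. Both primitives were
validated against reference DSP implementations to machine precision
during development.

**Envelope normalization scope.** The NASE mean is computed over the
*analyzed segment*: the whole recording for the base algorithm, each
clean interval separately after cropping. Recomputing per clean interval
matters — a loud burst inflates the global mean enough to push quiet
heart sound lobes below the threshold, which is precisely the failure
mode cropping repairs. When no lobe is flagged, the noise-robust variant
runs the identical code path on the full recording and returns
bit-identical labels to the base algorithm.

**Outlier pass structure.** Outlier statistics are computed once over
all detected lobes (single pass, population $1/M$ variance as the
formulas are stated). An iterative mode (`outlier_iterate = TRUE`)
re-screens after each removal; it is off by default since the published
pseudocode suggests one pass. Note the z-score of a single extreme among
$M$ lobes is bounded by $(M-1)/\sqrt M$, so nothing can exceed the 2.75
cutoff with fewer than about ten lobes — short or sparse recordings are
intrinsically outside this detector's reach.

**Interval semantics.** The 50 ms split rule uses the *gap*
(`next.start − prev.end`); cycle and systole lengths are onset-to-onset,
as is the "longest interval" that anchors identification. The scoring of
a candidate pair against the pair it extends treats a zero onset
distance (self-comparison) as a perfect cycle match. Ties at the best
score resolve to the earliest-onset pair.

**Accuracy matching.** "Corresponding" sounds for the midpoint-distance
accuracy are formed by greedy one-to-one matching in ascending midpoint
distance; an exhaustive oracle confirms it on small cases. Predicted
sounds outside the truth-annotated span are disregarded by both metrics,
since segmenters can legitimately find cycles where no ground truth
exists.

## The synthetic generator

`synth_pcg()` emulates exactly the structure the segmenter assumes:

- S1/S2 as Gaussian-windowed sinusoids (defaults 100 ms at 80 Hz and
  80 ms at 140 Hz, amplitudes 1 and 0.75) — band-limited bursts inside
  the 40–500 Hz passband with realistic durations;
- a constant systolic fraction of the cycle (default 0.35) with cycle
  jitter applied *to diastole only* (default relative SD 0.05), enforcing
  the systole-stability premise the identification logic relies on;
- optional split S1 (< 50 ms gap, unequal RMS), band-limited murmur
  noise across systole, and high-energy broadband bursts anywhere in the
  recording (`gain` 10 bursts carry an RMS ~15–20× the heart sound
  background);
- white background noise at 30 dB SNR by default — a quiet but not
  sterile recording.

What it does **not** emulate: real valve-sound morphology and frequency
chirps, respiratory modulation, S3/S4 gallops, holosystolic murmurs that
bury S2, sensor coupling artifacts, or drifting heart rates. A green
test on synthetic data therefore establishes that the implementation is
faithful to the stated rules and robust in the stated noise model — not
clinical-grade performance on hospital recordings. Gallop rhythms and
holosystolic murmurs are known failure modes of the underlying method
and are out of scope here too.

## Numerical notes and degenerate inputs

- Shannon energy guards squared-amplitude underflow (`x^2 == 0` for
  subnormal `x`), which would otherwise produce `0 · (−∞)` NaNs.
- Preprocessing is exactly amplitude-scale invariant (normalization is
  last), hence so is segmentation.
- Preprocessing is *near*-idempotent, not exactly: a second bandpass
  pass nibbles at the band edges (the realized magnitude response is
  squared). Tests budget a 5 % RMS difference for a mid-band signal.
- Silence and too-short recordings yield failure segmentations from the
  top-level entry points, not exceptions; constructors of recordings
  reject non-finite samples outright.
- Filtering a signal shorter than three filter orders of padding is an
  error; envelope computation requires at least one full window.

## Worked check

```{r}
s <- synth_pcg(synth_config(duration_s = 10, bpm = 90, seed = 42,
                            bursts = list(c(4, 5, 10))))
seg <- segment_noise_robust(s$recording)
glance(seg)
tidy(evaluate_segmentation(seg, s$truth))
```

```{r, fig.width = 7, fig.height = 3}
plot_segmentation(s$recording, seg)
```
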