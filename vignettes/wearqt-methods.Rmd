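---
title: "Methods: from device packets to QT dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from device packets to QT dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(wearqt)
```

wearqt re-creates, at desk scale, the software stack of a wearable
12-lead electrocardiograph: the binary telemetry format, lead derivation,
signal conditioning, beat detection and delineation, and a multi-lead
ventricular-repolarization analysis whose headline outputs are the
corrected QT interval (QTc) and QT dispersion (QTd). Because no recorded
data ship with the package, a ground-truth-labelled synthetic generator is
a first-class module: every stage of the pipeline is exercised against
signals whose fiducials are known by construction.

## The telemetry format

The device emits fixed 40-byte frames: a 3-byte sync word
`AA FF F1`, a length byte fixed at 34, eight channels (I, II, V1–V6) as
little-endian int32 raw counts, two lead-off flag bytes, and two
checksums. Checksum 1 is the sum of the preceding 38 bytes modulo 256.
The device documentation calls checksum 2 only "cumulative"; wearqt
defines it as the running modulo-256 sum of all checksum-1 bytes since
stream start, reset when a session starts — the simplest stateful reading
of "cumulative". Bit *i* of the first flag byte marks channel *i + 1*
(in transmission order I, II, V1–V6) as disconnected; the second flag
byte has no published bit assignment and is carried verbatim.

Decoding never throws on corrupted input: `decode_packet()` returns a
typed reject (`bad_header`, `bad_length`, `bad_checksum`) and
`resync_stream()` slides one byte at a time until a frame verifies, so a
flipped byte costs at most that frame. A spurious sync word inside junk
fails its checksum and is skipped.

## Lead derivation

With electrode potentials available, the 12 standard leads follow the
classical Einthoven–Goldberger–Wilson combinations, with the Wilson
central terminal $WCT = (RA + LA + LL)/3$ referencing the chest leads.
The device, however, transmits leads I and II rather than raw limb
potentials, so the remaining limb leads are computed from the algebraic
identities $III = II - I$, $aVR = -(I+II)/2$, $aVL = I - II/2$,
$aVF = II - I/2$, which are exactly equivalent under the WCT definition.
Both paths are implemented and tested against each other. The validity
mask of a derived lead is the conjunction of its sources' masks, so a
lead-off sample can never silently contribute to a derived lead.

## Conditioning

Raw counts become microvolts through the computed front-end constant
$2 \cdot V_{ref} / 2^{24} \approx 0.286\ \mu V$ per count
($V_{ref} = 2.4$ V, unity gain). Conditioning is a zero-phase chain:
order-2 Butterworth high-pass at 0.5 Hz (baseline/DC), a Q = 30 biquad
notch at the configured mains frequency (default 50 Hz), and an order-4
Butterworth low-pass at 125 Hz. The filter family and orders are the
package's own choices — standard ECG practice — since only the cutoffs
are fixed by the device documentation; forward–backward application
keeps fiducial latencies unshifted, which matters directly for QT.
No `signal`-processing package is assumed: the Butterworth bilinear
design, the notch and `filtfilt` live in the package.

Masked samples are never allowed to leak through filter state: each
contiguous valid run is filtered in isolation, and runs shorter than 1 s
are invalidated rather than filtered (the high-pass cannot settle).
Lead-off runs additionally carry a 250 ms guard band on both sides,
chosen at the filter-settling scale.

## Beat detection and delineation

R peaks come from a Pan–Tompkins-style chain (5–25 Hz band-pass,
differentiate, square, 150 ms moving-window integration, adaptive
signal/noise thresholds). The device rule that matters downstream is the
refractory interval: candidates closer than 0.4 s to an accepted peak
are suppressed, the larger integrated amplitude winning the slot. A
spacing of exactly 0.4 s is accepted ("closer than", not "at").

Per beat, Q onset is found by a backward threshold search from the Q
trough, the J point symmetrically forward from the S trough, and the T
peak as the largest deflection from the PQ baseline (the mean over the
40 ms ending at Q onset) in a window 80–400 ms after J. The T end uses
the tangent method: the steepest post-peak tangent intersected with the
baseline. Two numerical details are deliberate. First, the inflection is
located on a smoothed derivative and the tangent's slope and anchor come
from a local least-squares line fit (±14 ms); using the raw
single-sample derivative systematically overestimates the slope under
noise and pulls the T end ~20 ms early. Second, onset/offset thresholds
use the fraction $e^{-2} \approx 0.135$ of the wave amplitude — the
two-sigma point of a Gaussian wave — which makes the delineator's
conventions exactly consistent with the generator's ground truth.

Cycle exclusion follows the quality policy: `low_t_amplitude` when
$|T_{amp}| < \max(50\ \mu V,\ 3 \cdot \mathrm{noise}_{rms})$ (noise
estimated as $1.4826 \times$ MAD of the PQ segments); `ambiguous_morphology`
for U-wave suspicion (a same-sign deflection ≥ 25% of the T amplitude
within 200 ms after the tentative T end) or a biphasic T;
`tend_undetectable` when the tangent fails to cross baseline within
250 ms of the T peak. Two adjustments against false positives, both
package design choices: the biphasic test requires the opposite-polarity
deflection to exceed $\max(3 \cdot \mathrm{noise}_{rms},\ 0.25 |T_{amp}|)$
— a literal 3-sigma rule would randomly condemn clean beats, since the
maximum of ~150 noise samples routinely exceeds 3 sigma — and the U-wave
window is capped at 250 ms before the next R peak so the following P
wave is not mistaken for a U wave at higher heart rates. Sample indices
are 1-based (R convention); all reported intervals are differences, so
values are unaffected.

## Repolarization analysis

QT is measured on every non-excluded cycle as T end minus Q onset. Per
lead, robust outlier filtering precedes the estimate: the MAD rule drops
values more than $3 \times 1.4826 \times \mathrm{MAD}$ from the median,
falling back to the Tukey IQR fence (1.5 × IQR) when the MAD collapses
to zero. A lead is *eligible* when the retained count reaches 30 **or**
50% of all cycles in the fragment — read as a logical OR of two
sufficiency branches — and its estimate is the median of the retained
values. QT dispersion is max − min of the eligible per-lead medians over
the considered leads (I, II, V1–V6), reported only when at least 6 leads
qualify; otherwise it is `NA`, never a number computed from unreliable
data. The recording-level QT is anchored to lead II (the standard rhythm
lead), and Bazett's correction $QTc = QT / \sqrt{\overline{RR}}$ uses the
fragment-mean RR, giving one QTc per posture recording. Postures are
always analysed separately; nothing is pooled across them.

`NA` propagates: an ineligible lead II makes QT and QTc `NA` while QTd
may still be reported, and a fully lost recording produces an all-`NA`
feature vector rather than an error.

## The synthetic world

The generator builds beats as sums of Gaussian waves (P, Q, R, S, T,
optional U). This model was chosen over dynamical-system simulators
precisely because its fiducials have closed forms: the steepest-tangent
intersection for a Gaussian T of width $\sigma_T$ falls exactly at
$t_{peak} + 2\sigma_T$, and two-sigma amplitude crossings define wave
onsets, so the generator can place waves such that
(true T end − true QRS onset) equals the requested per-lead QT exactly.
Defaults state the emulated world: 60 s fragments at 500 Hz, heart rate
70 bpm with 60 ms RR jitter (a normal SDNN), 8 µV additive noise, 50 µV
baseline wander at 0.2 Hz, 10 µV mains, QRS 90 ms, QT 400 ms, per-lead R
and T amplitudes in typical adult ranges. Lead-off episodes zero the
channel (open circuit) and set the per-frame flag bits, so masking
failures are visible downstream. All randomness is fixed by a single
seed; identical seeds give identical recordings.

What the generator does *not* emulate — and therefore what a green test
does not establish — includes real T-wave morphologies (notched,
low-slope, non-Gaussian tails), respiration-coupled baseline and
amplitude modulation, ectopy and rhythm disturbances, electrode motion
artifacts, and inter-subject variability. Recovery results on this world
validate the pipeline's internal consistency, not clinical accuracy.

## Numerical choices and degenerate inputs

* Microvolt-to-count conversion rounds half to even, bounding round-trip
  error by half a count (≈ 0.143 µV).
* Zero-phase filtering uses odd-reflection padding (up to 1000 samples);
  detector inputs shorter than 2 s are an error, a flat signal returns
  zero peaks.
* Rhythm metrics with fewer than 2 peaks (RR/HR) or 3 peaks (SDNN) are
  `NA` with the beat count recorded.
* Reference-range screening treats one-sided `<`/`>` bounds as exclusive
  (QTc of exactly 450 ms is out of range for men) and two-sided spans as
  inclusive; unknown sex applies the stricter male QTc bound.
* The session store is JSON (features, per-lead detail, pauses, stage
  counters and the full configuration snapshot), with `NA` as `null`;
  CSV export renders `NA` as empty cells.

## A worked example

```{r example, eval = FALSE}
g <- generate_recording(
  synth_beat_params(qt_ms = c(I = 380, II = 400, V1 = 390, V2 = 405,
                              V3 = 410, V4 = 420, V5 = 410, V6 = 400)),
  synth_session_params(seed = 42))
session <- run_analysis(g, posture = "sitting")
glance(session)
tidy(session$repol)
flag_against_reference(session$features)
autoplot(session$repol)
```

## Known limitations

The delineator targets the dominant, single-peaked T waves the generator
produces; genuinely biphasic or notched T waves are excluded rather than
measured, which is the conservative behaviour for dispersion estimates
but discards information a human reader might use. The adaptive
R-detector thresholds are tuned for resting recordings; exercise ECG is
out of scope. Bazett's correction is used for comparability and shares
that formula's known heart-rate bias: QTc is overestimated at fast rates
and underestimated at slow ones.
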