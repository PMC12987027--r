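# wearqt

Desk-scale software stack for a wearable 12-lead electrocardiograph,
written for signal-processing engineers and digital-health researchers
who need to exercise an ECG analysis pipeline — telemetry decoding
through QT dispersion — without access to the physical device or any
recorded patients.

The package implements:

* **Packet codec** — bit-exact encoder/decoder for the device's fixed
  40-byte frames (sync word `AA FF F1`, length 34, eight int32
  little-endian channels I, II, V1–V6, lead-off flag bits, modulo-256
  checksum plus a cumulative stream checksum) with one-byte-slide
  resynchronization; corrupted bytes are typed rejects, never errors.
* **Lead derivation** — the 12 standard leads from electrode potentials
  (Wilson central terminal $WCT = (RA+LA+LL)/3$, Einthoven and
  Goldberger combinations) or from the 8 transmitted channels via
  $III = II - I$, $aVR = -(I+II)/2$, $aVL = I - II/2$, $aVF = II - I/2$,
  with per-sample validity masks propagated through every derivation.
* **Conditioning** — counts to microvolts by the computed front-end
  constant ($2 V_{ref}/2^{24} \approx 0.286\ \mu V$/count), then
  zero-phase high-pass (0.5 Hz), mains notch (50/60 Hz) and low-pass
  (125 Hz), applied per contiguous valid run so lead-off samples never
  contaminate filter state.
* **Rhythm and morphology** — Pan–Tompkins-style R detection with a
  0.4 s refractory rule, RR/HR/SDNN, and per-lead medians of P duration,
  QRS width, T amplitude and ST shift.
* **Repolarization** — per-cycle QT (Q onset to tangent-method T end),
  robust MAD/IQR outlier filtering, per-lead eligibility
  (≥ 30 valid cycles or ≥ 50% of the fragment), Bazett
  $QTc = QT/\sqrt{\overline{RR}}$, and QT dispersion
  $QTd = \max(QT_{lead}) - \min(QT_{lead})$ over eligible leads,
  reported as `NA` unless at least 6 leads qualify.
* **Feature screening** — the assembled feature vector flagged against
  shipped adult reference ranges (e.g. QTc < 450/470 ms, QTd < 50 ms),
  and beat-level T-end agreement statistics (mean Δ, MAE, SD) for
  comparison against expert annotation.
* **Synthetic device** — a ground-truth-labelled Gaussian-wave ECG
  generator and packet-stream simulator, so every rule above is testable
  end to end with known fiducials.

## Worked example

```r
library(wearqt)

g <- generate_recording(
  synth_beat_params(qt_ms = c(I = 380, II = 400, V1 = 390, V2 = 405,
                              V3 = 410, V4 = 420, V5 = 410, V6 = 400)),
  synth_session_params(seed = 42))          # 60 s, 500 Hz, HR 70
session <- run_analysis(g, posture = "sitting", recording_id = "demo-42")
session
#> <session_record> demo-42 (synthetic)
#>   beats: 69   pauses: 0
#>   HR 69.8 bpm  QT 402.0 ms  QTc 433.7 ms  QTd 42.0 ms
```

The generated per-lead QTs span 380–420 ms, so the true dispersion is
40 ms; the pipeline measures 42 ms. `tidy()` exposes the per-lead
detail, `glance()` the recording-level summary:

```r
tidy(session$repol)
#> # A tibble: 8 × 6
#>   lead  qt_median_ms n_valid n_total eligible ineligibility_reason
#> 1 I              380      63      69 TRUE     none
#> 2 II             402      68      69 TRUE     none
#> 3 V1             390      58      69 TRUE     none
#> 4 V2             406      69      69 TRUE     none
#> ...

flag_against_reference(session$features)
#> # A tibble: 7 × 3
#>   parameter          value flag
#> 1 rr_mean_ms     859.      in_range
#> 2 sdnn_ms         67.2     in_range
#> 3 qt_ms          402       in_range
#> 4 qtc_ms         434.      in_range
#> 5 qtd_ms          42       in_range
#> 6 t_amplitude_mv   0.304   in_range
#> 7 st_shift_mv      0.00544 in_range
```

Here QT is the lead II median (true value 400 ms), QTc applies Bazett's
correction with the fragment-mean RR of 0.859 s, and every screened
parameter sits inside its reference range — the generated profile is a
healthy one. `autoplot(session$repol)` draws the per-lead medians with
eligibility; `autoplot(g$recording)` the raw channels.

A thin CLI over the same functions lives in `inst/cli/wearqt-session.R`
(verbs `simulate`, `decode`, `analyze`, `report`).

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the toolkit's deterministic design thresholds: the smallest
number of quality-eligible leads that yields a numeric QT dispersion
(sweeping clean-lead counts over synthetic recordings), the smallest
valid-cycle count that makes a lead eligible in a 100-cycle fragment,
and the minimum accepted R-peak separation (sweeping two-beat gaps in
10 ms steps). Run it as:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

The package computes features and flags only — no classifier, risk score
or diagnostic output. Postures are analysed independently. Alternative
QT corrections (Fridericia, Framingham), Tp–e indices and HRV beyond
SDNN are out of scope. See `vignettes/wearqt-methods.Rmd` for the full
methods account, design decisions and limitations.
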