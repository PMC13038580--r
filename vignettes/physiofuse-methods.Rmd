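---
title: "Methods: multi-rate sensor fusion, device agreement, and the EEG cognitive pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-rate sensor fusion, device agreement, and the EEG cognitive pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiofuse)
```

physiofuse analyzes multi-device physiological monitoring sessions in
which wearable and reference sensors report one subject's physiology at
very different native rates, telemetry can drop out, and each device also
caches data on its own clock. This vignette is the package's account of
the models and numerical choices behind each stage, what the synthetic
session generator does and does not emulate, and the known limitations.

## Master-clock fusion

All streams are fused onto a single tick grid (default 200 Hz, the highest
native device rate) by *sample-and-hold*: the cell for stream $s$ at tick
$t$ holds the value of the latest valid sample of $s$ with timestamp
$\le t$. A sample timestamped exactly at a tick belongs to that tick
(closed right boundary). Cells are flagged `fresh` when their sample falls
inside the tick's own interval, `held` when it is a repeated placeholder,
and `missing` before a stream's first sample — back-filling would invent
pre-acquisition data, so it is off by default (`hold_before_first`).
No interpolation is ever performed at this stage: every fused value is an
actual device sample.

Numerical choices worth stating:

* Tick spacing is exactly `round(1e9 / rate)` integer nanoseconds, so the
  grid cannot drift over a session. Timestamps are doubles holding exact
  integers (exact below $2^{53}$ ns ≈ 104 days); validation checks
  integerness.
* Cell lookup is by timestamp comparison (`findInterval`), never index
  arithmetic: device rates are nominal ("approximately 38 Hz") and jitter
  is the norm.
* A grid derived from the data ends at the tick at or after the last
  sample, so no sample is unrepresented; an explicitly requested end bound
  is exclusive, `[t0, t1)`.
* `deduplicate_held()` inverts the expansion by returning only fresh
  cells. The inversion is exact for streams below the master rate; a
  stream at the master rate with sampling jitter can place two samples in
  one tick interval, where only the later survives — this is the stated
  "up to tick quantization" contract, not an error.

Sessions persist as structured JSON (`write_session()` /
`read_session()`), with doubles serialized at 17 significant digits so
the round trip is bit-exact, including per-cell freshness flags and the
event log.

## Cached-copy alignment

For a cached onboard copy on a device clock, the lag against the streamed
reference is estimated by normalized cross-correlation: both signals are
linearly resampled to a common grid (default 200 Hz), mean-removed, and
correlated over lags within a search window; a parabolic fit through the
three points around the integer-lag peak gives sub-sample resolution.
Normalization makes the estimate invariant to amplitude scaling between
copies, and the peak Pearson correlation is reported as a confidence. The
correlation window defaults to the full overlap but accepts a segment
restriction (e.g. a pre-baseline interval of stable transmission); the
window must exceed twice the lag search half-width, and flat signals are
rejected as undefined.

The fitted clock map is affine, `device = slope × reference + intercept`:
a single lag estimate gives a pure offset (drift 0); two or more anchor
pairs give offset plus drift (in ppm) by least squares on centered
coordinates. Gap patching re-timestamps the cache through the map and
fills only (a) inter-sample gaps in the streamed copy longer than 3× the
nominal period and (b) regions outside the streamed span. Streamed
samples are never modified; a cached sample within half a nominal period
of an existing streamed sample is treated as a duplicate and dropped,
which absorbs sub-sample clock-map error at gap edges.

## ECG heart rate

R peaks are detected with a Pan-Tompkins-style chain: zero-phase
Butterworth band-pass 8–20 Hz (order 3), differentiation, squaring,
150 ms moving-window integration, and adaptive signal/noise thresholds
(`thr = noise + 0.25 (signal − noise)`, exponentially updated) with a
250 ms refractory period. Two stages matter in practice:

* **Searchback.** A single beat rejected by the adaptive threshold
  inflates the noise estimate and can cascade into every-other-beat
  misses at high heart rates. RR gaps longer than 1.6× the local median
  RR are therefore re-searched at a reduced local energy level, the
  classic remedy. On noisy synthetic ECG (R-wave SNR ≈ 5) this raises
  sensitivity from ~96% to ~99.5% with unchanged PPV.
* **Peak refinement.** Detection operates on the integrated energy;
  locations are refined to the strongest band-passed deflection within
  ±150 ms, then the raw-signal maximum within ±25 ms, and amplitudes are
  read from the raw signal — so the detector is scale-invariant while
  amplitudes stay physical.

Instantaneous HR is 60/IBI, timestamped at the second beat of each pair.
Smoothing is a centered rolling mean over exactly 100 beats with
shrinking windows at the edges (down to one sample); it is
order-preserving by construction. Device-reported HR/PR values are
consumed as-is, never recomputed.

One subtlety for evaluation: phase means of a per-beat series overweight
fast-HR segments, because beat density is proportional to HR. Comparing
smoothed HR with a trajectory's time-average during a decaying recovery
shows an apparent ~5 bpm bias that vanishes when the smoothed series is
first interpolated onto a uniform time grid. All phase-mean checks in
this package therefore compare on a uniform 10 Hz grid.

## Device agreement

Paired analyses co-resample both series by linear interpolation onto one
shared 10 Hz grid spanning the protocol timeline (start tick included,
end excluded: 60 s → 600 pairs); pairs with either side missing are
dropped. Agreement is summarized by Pearson r (two-sided p) and
Bland-Altman statistics: bias = mean(a−b), SD of differences, limits of
agreement at bias ± 1.96 SD, and a proportional-bias slope from OLS of
the differences on the pair means. Pooling across subjects and
repetitions understates LOA uncertainty for repeated measures — the
per-subject stratified route is to compute `bland_altman()` per subject
and combine; the pooled form is what the package reports by default.

Phase-progress normalization maps each protocol phase onto a fixed
500-point 0→1 axis by linear interpolation (endpoints exact), enabling
element-wise group averaging (mean ± SEM, SD with n−1, SEM undefined at
n = 1). Occlusion traces instead resample each phase at 1,000 frames per
nominal minute with natural cubic splines (3 + 1 + 1 + 1 + 5 minutes →
11,000 frames); cubic interpolation preserves constants exactly and its
overshoot on monotone segments is bounded in tests at 1% of the phase
range.

## StO2 plausibility filtering

A sample is rejected below 5%, above 95%, or when it differs from the
last *accepted* sample by more than 20 points (first sample exempt).
Judging jumps against the last accepted — not last raw — sample prevents
a single spike from cascading rejections. Each rejection carries one
primary reason with precedence low > high > jump, so reason counts
partition the rejections. The jump rule is per-sample (device rates
differ; a per-second variant would need a rate argument) and the
threshold is configurable. Placement error against a reference site is
the per-tick signed percent difference on mutually accepted, time-matched
samples; both the signed mean and the mean absolute value are reported,
since an "error rate" has no canonical sign convention.

## EEG cognitive pipeline

**Filtering.** Linear detrend, then a zero-phase Butterworth band-pass
realized as an order-4 high-pass at 0.1 Hz cascaded with an order-4
low-pass at 30 Hz, each applied forward-backward. The cascade is used
because a direct 8-pole band-pass with a normalized edge of 8×10⁻⁴ is
numerically fragile in transfer-function form; the cascade has the same
band and zero phase.

**Blink removal.** Blinks are detected on the ≤4 Hz low-passed frontal
channel as peaks above median + 4·MAD with ≥500 ms separation (adaptive,
hence amplitude-scale invariant). ICA is fit on concatenated ±500 ms
segments around the blinks — where the blink source dominates, making it
identifiable even on an 8-channel montage — and the unmixing weights are
transferred to the full continuous recording. The component most
correlated with the low-passed frontal channel inside the segments is
zeroed and the data remixed. The ICA engine is a deflation FastICA (tanh
contrast) written for this package: units are extracted one at a time, so
the strongly non-Gaussian blink source converges first; later units
spanning the near-Gaussian background may not converge, which is harmless
because removing one component is invariant to how the remaining
orthonormal basis is rotated. Non-convergence of the blink-correlated
unit itself is an error. The engine is pluggable (`ica` argument).

**Epoching and rejection.** Epochs span −1,000..1,500 ms around stimulus
and response markers. An epoch×channel cell is flagged at |amplitude| >
100 µV or when Welch band power in 20–40 Hz exceeds 50 dB re 1 µV²/Hz
(Hann windows, 50% overlap). Both rules are evaluated independently, and
a cell's reason can be "voltage+spectral": under this absolute dB
reference any signal crossing 50 dB also crosses 100 µV, so making the
rules exclusive would hide the spectral flag. An epoch is rejected if any
retained channel is flagged; masks are deterministic given data and
thresholds.

**Channel and participant hygiene.** Channels flagged in >20% of epochs
are excluded and rebuilt by spherical-spline interpolation (Perrin-style,
order m = 4, 20 Legendre terms, standard 10–20 unit-sphere positions for
the 8-electrode montage), then their flags cleared and epoch rejection
recomputed. The participant rule is applied literally: interpolated
channels >10% of channels excludes the participant — with 8 channels a
single interpolation is 12.5%, so any interpolation excludes. Because
that literal reading is arguably harsher than intended on small montages,
`participant_rule = "rounded"` tolerates up to `round(0.10 × n)`
channels; the literal rule is the default.

**Time-frequency.** Complex Morlet wavelets at 20 linearly spaced
frequencies 2–30 Hz with cycle counts log-spaced 3→6, unit-energy
normalized, convolved per trial via FFT; power is the squared magnitude.
Samples within half a wavelet length of an epoch edge are flagged
unreliable per frequency. Note 16 Hz lies exactly midway between the
15.26 and 16.74 Hz bins of this grid — "the nearest bin" is a tie there.
Power is baseline-normalized divisively per trial:
$10\log_{10}(P / \bar P_{\text{baseline}})$, where the baseline is that
same trial's stimulus-locked mean power over −400..−100 ms; response-
locked epochs inherit their own trial's stimulus baseline, so both locks
share a per-trial reference and the baseline window maps to 0 dB by
construction. Condition averages are taken after single-trial
normalization. A `decim` argument (default 4) thins output time samples
to bound memory; power at kept samples is unaffected.

**Trial classification.** Correct/error by response key against the
color→key map; responses with RT > 500 ms are late and excluded (a
response at exactly the boundary is included), absent responses are
missed and excluded. Responses during the 800–1,200 ms RSI are recorded
but remain late.

## The synthetic session generator

The generator produces the study conditions the pipeline assumes, with a
ground-truth sidecar sufficient to score every estimator (beat times,
injected offsets and dropouts, blink peak times, burst trials).

* **Protocols** are the two bench protocols: occlusion 180/60/60/60/300 s
  at 0/100/150/200/0 mmHg, and the exercise ramp 120 s rest, 120 s each
  at 50–60/60–70/70–80% HRmax, 240 s recovery.
* **HR dynamics** are first-order exponential approaches to each phase's
  zone midpoint (τ = 30 s by default — a physiological on/off kinetics
  scale; the protocols specify only target zones). Beats are placed by
  integrating the instantaneous rate, so HR(t) is exactly recoverable
  from the IBIs. The ECG is a stylized Gaussian-bump PQRST template
  (R = 1 mV) plus white noise; motion segments add broadband noise and
  sinusoidal baseline wander scaled by a degradation factor. Degradation
  factors are free parameters — no device noise calibration exists to pin
  them.
* **Device models** apply reporting rate, constant bias, response lag,
  white jitter, Bernoulli dropout, and a clock offset for cached copies.
* **StO2 kinetics**: plateau at 70%, pressure-proportional linear
  desaturation (0.1 %/min per mmHg default — 200 mmHg drains ~20 %/min),
  exponential recovery (τ = 30 s) with an alpha-function reperfusion
  overshoot (5%, peaking at 30 s) that fires only after an actual oxygen
  deficit; values clipped to [0, 100].
* **Simon-task EEG**: pink-noise background (8 µV), 10 Hz posterior
  alpha, 300 ms raised-cosine blinks (80 µV at Fz), and 6 Hz Hann-
  windowed theta bursts over 0–400 ms post-response on error trials only.
  RTs are truncated log-normal within the 500 ms window with
  configurable late/miss probabilities; 160 trials per block.
  The spatial patterns are deliberately distinct: the blink falls off
  steeply from Fz backwards (>4:1, the ocular dipole is far anterior)
  while error theta peaks at Cz/FCz. An earlier draft used nearly
  collinear patterns and blink-component removal then cancelled most of
  the theta contrast — a useful reminder that blink ICA *does* remove
  whatever midline activity projects onto the blink component. Real
  montages with true EOG leads separate these sources better than 8 dry
  channels can.

What passing tests on this generator do *not* show: real ECG morphology
variation (ectopy, electrode pop, muscle noise), true NIRS optical
physics, non-stationary EEG rhythms, or realistic blink waveform
variability. The generator is statistical plumbing for estimator
validation, not a biophysical model.

## Problem sizes and reproducibility

Simulated sessions in the test-suite and in `scripts/acceptance.R` are
sized for tight, informative statistics at desk scale: 12-minute exercise
ramps (~1,100 beats), 25–100 alignment sessions of 90 s, 6,000 agreement
pairs (jitter propagation needs n ≥ 5,000 for a 10% band on σ√2), and
two 160-trial Simon blocks for the ERSP contrast (one block leaves the
error-trial theta estimate seed-unstable; two blocks is also the
per-sitting count of the task design). All randomness flows from explicit
seeds; `run_pipeline()` writes byte-identical artifacts for identical
configurations, verified by MD5 manifest.

## Known limitations

* The alignment model is affine (offset + drift); nonlinear clock warping
  is out of scope.
* Pooled Bland-Altman on repeated measures understates LOA width; the
  stratified route is manual.
* The spectral rejection reference (dB re 1 µV²/Hz band mean) makes the
  50 dB rule redundant with the 100 µV rule for physiological amplitudes;
  it catches only gross artifacts, which matches its role as a second
  line of defense.
* Spherical-spline interpolation on an 8-channel montage is a coarse
  reconstruction; with ≤6 remaining channels it errors rather than
  fabricating a field.
* The FastICA engine extracts at most `n_channels` components and assumes
  one dominant blink source; overlapping ocular sources (blinks plus
  saccades) would share a component.
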