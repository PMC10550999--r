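---
title: "Quantifying porpoise responses to acoustic harassment devices from tag data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying porpoise responses to acoustic harassment devices from tag data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acoustic harassment devices (AHDs, "seal scarers") emit intense 14-kHz
pulses (500 ms, source level ~189 dB re 1 µPa rms @ 1 m, random intervals of
0.6–90 s) to deter pinnipeds, and are increasingly used to push harbour
porpoises out of pile-driving zones before construction starts. Multi-sensor
suction-cup tags (stereo audio at 240–576 kHz, triaxial acceleration,
pressure, and for some tags ECG or GPS) record both the dose each animal
actually receives and its behavioural and physiological response. `ahdtag`
implements the complete tag-data analysis for such exposures: acoustic
dosimetry, echolocation metrics, movement metrics, dive and respiration
analysis, heart-rate extraction, track kinematics, propagation modelling,
and the per-animal response table that summarizes a 15-min exposure against
the 15 min immediately preceding it.

Every stage can be exercised end to end on synthetic deployments with known
ground truth, because raw tag deployments of this kind are rarely shareable.

## Dosimetry model

Received AHD pings are measured on audio that has been band-pass filtered to
10–46 kHz (6-pole Butterworth), wide enough to keep the 14-kHz fundamental
and its first two harmonics (28, 42 kHz) while rejecting low-frequency flow
noise and the animal's own ~130-kHz clicks. Three quantities are computed
per ping:

* **rms-fast RL** — the square root of the mean squared pressure over a
  125-ms window, in dB re 1 µPa. The original window placement is not
  specified, so the default slides the window across the ping and reports
  the maximum (max-hold); an onset-anchored window is available
  (`measure_rl_rms_fast(anchor = "onset")`). For a ping longer than 125 ms
  the two agree to a small fraction of a dB.
* **single-ping SEL** — `10 log10( ∫ p² dt )` over 500 ms from onset, in dB
  re 1 µPa²s, kept at the emitted duration even when shallow-water
  multipath stretches the received ping (a longer integration window is a
  parameter for sensitivity analysis).
* **SNR** — ping rms against the rms of the 125 ms immediately preceding
  the onset, in the same band. Only pings with SNR strictly above 10 dB are
  accepted for level evaluation.

The cumulative dose is a non-leaky energy sum over accepted pings,
`SELcum(k) = 10 log10 Σ_{i≤k} 10^(SEL_i/10)`; ignoring auditory recovery
makes it an upper bound on the effective dose. Risk of a temporary
threshold shift (TTS) is flagged against a single-pulse onset of
142 dB re 1 µPa²s, both as outright exceedance and as coming within a
configurable margin (default 3 dB) of it — "close to the limit" is reported
separately from "over the limit".

Ping detection is an envelope-threshold detector on the 12–16 kHz sub-band
(noise median + 10 dB, minimum gap 0.5 s, onset at the first threshold
crossing). The original workflow marked pings manually; any function that
consumes ping times accepts manually marked times instead, and
`apply_review()` implements accept/reject edits.

## Echolocation

Porpoise clicks are narrow-band high-frequency (~130 kHz) transients.
Apparent output level is the peak-to-peak pressure in a 20-ms segment
around each detection after an 80-kHz 6-pole high-pass, reported in dB re
1 µPa pp. Levels are *apparent* — they depend on tag placement — so the
package never compares them across deployments; the built-in comparison is
the within-deployment difference of 95th percentiles (exposure minus
control), the percentile chosen because maximum output is what matters for
acoustic crypsis. Click detection requires a sampling rate of at least
260 kHz (twice the click band); on slower mid-frequency tags the click
cells of the response table are undefined rather than unreliable, while
buzzes remain analysable from spectrograms (`buzz_audit_spectrogram()`
exports the Hamming/512/75%-overlap view used for manual verification).

Feeding buzzes are maximal runs of at least 5 clicks with all inter-click
intervals below 15 ms *and* a jerk transient within 1 s of the run — the
movement criterion that separates prey captures from social calls with
similar ICIs. The run length (5) and jerk gate (twice the deployment median
jerk) are unstated in the original protocol; both are parameters.
Resumption of feeding is the time of the fifth buzz strictly after a
reference event, which is insensitive to a single mis-classified call.

## Movement, startle, dives, respiration

Accelerometry is decimated to 25 Hz (zero-phase 4-pole low-pass at 0.4× the
target rate, then stride sampling). Two derived series drive the analysis:

* **MSA** `= | ‖a‖ − 9.81 |` (m/s²), an orientation-free lower bound on
  specific acceleration; its 95th percentile over 5-s bins is the swimming
  -effort proxy, and the effort cell of the response table is the percent
  change of the window mean of those bins.
* **Jerk** `= ‖Δa‖ · 25` (m/s³); sharp transients mark prey captures and
  the whole-body flinch of the acoustic startle reflex.

A ping counts as startling when the jerk peak within 0.2 s *after its
arrival at the tag* exceeds the mean + 3 SD of the 10 s preceding it.
"Significant peak" is not defined in the original; mean + 3 SD is the
package's reconstruction and both the window and the gate are parameters.
The 0.2-s window is anchored at arrival (not emission) because at 7 km the
travel time (~4.7 s) would otherwise swallow the reflex window. The
deployment-level startle flag summarizes the first five accepted pings.

Dives are maximal intervals deeper than 0.5 m; a dive is U-shaped when at
least half of it is spent at ≥85% of its maximum depth (V when ≤20%).
Visual crypsis is time within 2 m of the surface or of the *apparent
seafloor* — a bathymetry grid looked up along the GPS track when available,
otherwise the interpolated maximum depths of U-dives, which approximate the
local bottom. Respirations are broadband 0.1–4 kHz transients detected on
audio decimated to 12 kHz, gated to moments when the animal is within 1 m
of the surface; the working rate and band keep the 14-kHz ping (and
anything it could alias onto) far outside the blow band.

## Heart rate

ECG is decimated to 250 Hz and band-passed 1–10 Hz (4-pole), which keeps
the QRS complex and removes wander and mains. R-peaks come from adaptive
thresholding (half of the running 5-s envelope maximum, capped at 1.5× the
median block maximum so filter edge artifacts cannot blind a block) with a
0.25-s refractory period (supports up to 240 beats/min), refined to
sub-sample precision by parabolic interpolation — without the refinement
the 4-ms sample grid alone would exceed a 2-bpm error budget at high rates.
Instantaneous heart rate is exactly `60 / RR`, assigned at the end of each
interval (causal, convenient for event-locked analyses of post-ping
tachycardia). Window summaries report 10th/90th percentiles and medians,
plus a running 50-s median for diving heart rate.

## Tracks and propagation

Leg speeds are geodesic distance over elapsed time between GPS fixes; legs
above 5 m/s (well beyond porpoise top speed) mark an erroneous fix — the
later fix of the first offending leg is dropped and speeds recomputed
across the gap, iterating until clean. Transmission loss is
`k log10(R) + α R/1000` with spherical (k = 20) or cylindrical (k = 10)
spreading and absorption α (default 1.5 dB/km); `solve_effect_range()`
inverts it by root bracketing on [1 m, 100 km], and `impact_area_ratio()`
turns radii into the `(r1/r2)²` area factors used in mitigation arithmetic.
The empirical dose-range relation is the median rms-fast RL of the five
pings nearest in time to each fix, against the range at that fix.

The "fled" cell of the response table is a robust (Theil–Sen) trend of
accepted ping RLs over the exposure below −0.2 dB/min, or a positive GPS
range trend; both indicators are reported and either suffices.

## The response table

`analyze_deployment()` compares the exposure against a control window of
equal length immediately before it (both capped at 15 min; when the
exposure or the pre-roll is shorter, both shrink together). Percent changes
are rounded half away from zero to integers; click levels are differenced
in dB. Undefined cells (no clicks measurable, too few pings) stay undefined
and are never counted. The response index counts, irrespective of
direction, the boolean criteria that are TRUE (startle, fled, TTS risk) and
the numeric cells whose magnitude reaches 8 (% / percentage points / dB).
The threshold is a reconstruction — it is the unique simple rule consistent
with the published per-animal indices — and is exposed as
`index_threshold`. Group summaries average swimming effort over the fleeing
animals, click-rate change over the animals that decreased, crypsis over
all defined cells, and speed over the supplied per-animal increases.

## The synthetic generator

`generate_deployment()` renders a full deployment from a
`scenario_config()` and logs every generated event as ground truth:

* pings as 14-kHz tone bursts with 5-ms cosine ramps and harmonics at −20
  and −30 dB (the harmonic frequencies are documented for the device, their
  levels are not; the fast rise time is what matters for startle realism),
  received at levels set by the instantaneous range through the configured
  propagation model, with an optional exponential reverberation tail
  mimicking shallow-water stretching (off by default);
* clicks as 50-µs Gaussian-enveloped 130-kHz pips — the standard NBHF
  surrogate — with exact programmed peak-to-peak levels; buzzes as fast-ICI
  runs coupled to a jerk transient, and optional "social" runs without one;
* fluking as a 1.4-Hz sinusoid whose amplitude scales with speed (or is set
  per phase), startle flinches as 0.12-s half-sine bumps after selected
  ping arrivals, Gaussian sensor noise;
* dive cycles whose surface/bottom split is solved analytically to hit a
  programmed crypsis fraction over a flat seafloor; respirations placed
  deterministically within surface intervals at the scheduled rate and
  rendered as band-limited (0.15–3.5 kHz) transients;
* a stylized ECG (QRS template dominated by the R peak, which is all the
  pipeline uses) whose beat times integrate a programmed instantaneous-rate
  schedule; GPS fixes subsampled every 180–300 s from the true track with
  5-m isotropic position noise (tag fix precision is not documented);
* broadband flow noise at 85 dB re 1 µPa (a quiet-sea floor that leaves
  distant pings above the 10-dB acceptance SNR, as in the reported
  deployments).

A fixed seed reproduces the deployment bit for bit. What the generator does
*not* emulate: real propagation (multipath, bathymetry-dependent loss),
click directionality and tag-placement effects, behavioural feedback
between dose and movement within a phase, tag slides, or ECG morphology
beyond R timing. Passing recovery tests therefore demonstrates that the
estimators invert the generative model they assume, not that they are
robust to every artifact of real recordings — which is why every detector
also accepts manually marked events as first-class input.

One documented inconsistency is deliberately left alone: the device's
stated single-ping source SEL (184 dB re 1 µPa²s) is about 2 dB below
`SL + 10 log10(0.5 s) = 186`; pings are synthesized from the SL and the
discrepancy is not reconciled.

## The six-scenario battery

`scenario_battery()` programs six animals with the observed direction
pattern: four startle, five flee, click rates drop in four and rise
sharply in one, two drop output by 8 dB, one animal instead dives quietly
with reduced effort, and the three closest exposures accumulate doses at or
near the TTS reference. Animal 6 carries a 240-kHz mid-frequency tag, so
its click cells are undefined by construction. The end-to-end test asserts
that the pipeline reproduces every programmed flag and sign.

The battery's full design uses 15-min windows; the shipped tests and the
acceptance script run it at 60-s windows with ping intervals capped at
window/10 and exposure ranges set so the programmed TTS pattern is
expressed within the shortened dose accumulation. Respiration rates are
chosen so the programmed direction survives breath-count quantization at
that window length. These problem sizes (and the 120-s dosimetry scenario,
300-s heart-rate ramp, and 20 × 700-s flinch-free startle runs) keep the
whole validation battery comfortably reproducible on a laptop; all scale
back up through `scenario_config()` without code changes.

## Numerical choices

* All pressures are stored in Pa; dB conversions go through one helper pair
  (`pa_to_db()`/`db_to_pa()`) with the 1-µPa reference in a single place.
* Filters are Butterworth designs applied through a compiled direct-form-II
  kernel; zero-phase (forward–backward, reflected-edge padding) for level
  measurement, causal for onset timing.
* Decimation uses the nearest-integer factor, so the achieved rate can
  differ from the request by sample rounding and is always returned.
* Percentiles are linear-interpolation (type 7) throughout.
* Empty windows, zero baselines and missing streams propagate as flagged
  `NA`s, not errors, and undefined cells never enter indices or means.
* `solve_effect_range()` flags (rather than extrapolates) thresholds
  outside [1 m, 100 km].

## Known limitations

Respiration and ping detectors are automated surrogates for what was
originally manual marking; on low-SNR recordings the review-table path is
the intended workflow. Seafloor estimation assumes U-dives reach near the
bottom and interpolates between them. The response-index threshold is a
reconstruction, not a published rule. Heart-rate analysis ignores ECG
morphology entirely. No hypothesis testing is provided across animals —
with six animals the table is descriptive, which is also why group
summaries are plain means over stated subsets.
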