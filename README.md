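# ahdtag

Analysis of sound-and-movement tag data from harbour porpoises
(*Phocoena phocoena*) exposed to an acoustic harassment device (AHD, "seal
scarer"): acoustic dosimetry, echolocation and movement metrics, dive,
respiration and heart-rate analysis, GPS kinematics, propagation modelling,
and a per-animal exposure response table. Written for marine bioacousticians
and biologging researchers who need to quantify what an animal actually
received from a deterrence source and how it responded.

AHDs transmit 500-ms, 14-kHz pulses at a source level (SL) around
189 dB re 1 µPa (rms) @ 1 m. Tags record calibrated audio (240–576 kHz),
triaxial acceleration, depth, and optionally ECG or GPS. The package
implements the full chain from raw streams to response table:

* **Dose** — pings are band-passed to 10–46 kHz (6-pole), each ping gets an
  rms-fast received level (RL, 125-ms window, dB re 1 µPa), a single-ping
  sound exposure level SEL = 10·log₁₀∫p²dt over 500 ms (dB re 1 µPa²s), and
  an SNR acceptance gate (> 10 dB). The cumulative dose is the non-leaky sum
  SELcum = 10·log₁₀ Σ 10^(SELᵢ/10), flagged against the single-pulse TTS
  onset of 142 dB re 1 µPa²s.
* **Echolocation** — ~130-kHz clicks detected after an 80-kHz high-pass;
  apparent output level = peak-to-peak pressure in a 20-ms segment (dB re
  1 µPa pp); click rates (cpm) and 95th-percentile levels per window;
  feeding buzzes = runs of clicks with inter-click intervals < 15 ms plus a
  jerk transient.
* **Movement** — minimum specific acceleration MSA = |‖a‖ − g| at 25 Hz;
  swimming effort = 95th percentile of MSA over 5-s bins; jerk = ‖Δa‖·25
  (m/s³); acoustic startle = significant jerk peak within 0.2 s of a ping.
* **Dive / crypsis / respiration** — dive segmentation, apparent-seafloor
  estimation from U-dives or bathymetry, visual crypsis (within 2 m of
  surface or seafloor), respiration events and rates.
* **Cardiac** — ECG → R-peaks → instantaneous heart rate fH = 60/RR.
* **Propagation** — TL = 20·log₁₀R (spherical) or 10·log₁₀R (cylindrical)
  plus absorption (dB/km); RL = SL − TL; effect-range solving and
  π·r² impact-area arithmetic.
* **Response table** — 15-min exposure vs the 15 min immediately before:
  startle, crypsis difference, click-rate and click-level change, MSA
  change, flight, respiration-rate change, TTS risk, and a response index
  counting effects irrespective of direction.

A seeded synthetic-deployment generator (`generate_deployment()`,
`scenario_battery()`) produces every stream with a complete ground-truth
event log, so all detectors are validated by recovery tests.

## Worked example

Simulate a tagged porpoise 680 m from an AHD that starts transmitting at
t = 60 s; the animal flees at 1.8 m/s with increased fluking, goes more
cryptic, and breathes faster:

```r
library(ahdtag)

cfg <- scenario_config(
  seed = 42, duration = 130, exposure_start = 60, exposure_end = 120,
  audio_fs = 120000, ahd = list(interval_range = c(0.6, 6)),
  position = list(start_range = 680),
  track = list(speed = c(1.3, 1.8), heading = c(0, 180)),
  dive = list(crypsis_frac = c(0.65, 0.80)),
  clicks = list(rate_cpm = 0),
  fluking = list(amp = c(1.2, 1.9)),
  respiration = list(rate = c(3.2, 4.2)),
  streams = c("audio", "accel", "depth"))
g <- generate_deployment(cfg)
res <- analyze_deployment(g$deployment)
res$dose
res$response
```

```
<exposure_dose> 16 pings, 16 accepted
  SELcum 140.2 dB re 1 uPa^2 s (TTS threshold 142, margin 3): within margin
               id startle crypsis_diff click_rate_change click_level_change
 synthetic_seed42    TRUE           14                NA                 NA
 msa_change fled resp_rate_change tts_risk response_index
         58 TRUE               33     TRUE              6
```

Reading the row: the animal startled to the first pings, spent 14
percentage points more time in visual crypsis during the exposure, increased
swimming effort by 58% and respiration rate by 33%, fled (decaying ping RLs),
and its 60-s dose of 16 pings reached 140.2 dB re 1 µPa²s — within 3 dB of
the TTS reference, so the hearing-risk flag is set. Click cells are
undefined (`NA`) because this scenario programs no echolocation; undefined
cells never count toward the response index (here 6 of 8 criteria).

Propagation what-ifs use the same functions the dose analysis uses:

```r
transmission_loss(1000)                      # 61.5 dB (spherical + 1.5 dB/km)
received_level(164, 1000)                    # ~102 dB re 1 uPa at 1 km
solve_effect_range(190, 100)                 # ~7976 m response range
impact_area_ratio(900, 300)                  # 9-fold impact-area reduction
```

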