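Package: ahdtag
Title: Dosimetry and Response Analysis for Porpoise Sound-and-Movement Tag
    Data from Acoustic Harassment Device Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing acoustic and movement data from
    suction-cup sound-and-movement tags deployed on harbour porpoises
    exposed to an acoustic harassment device (AHD, "seal scarer").
    Implements acoustic dosimetry of 14 kHz AHD pings (rms-fast received
    level over a 125 ms window, single-ping and cumulative sound exposure
    level, risk flags against a temporary-threshold-shift reference),
    echolocation click and feeding-buzz detection, accelerometry metrics
    (minimum specific acceleration, jerk, acoustic startle detection),
    dive segmentation and visual-crypsis classification, respiration
    detection, ECG R-peak extraction and instantaneous heart rate, GPS
    track kinematics, transmission-loss and impact-zone modelling, and
    assembly of a per-animal pre-exposure versus exposure response table.
    A seeded synthetic-deployment generator with full ground truth allows
    every stage of the pipeline to be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
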