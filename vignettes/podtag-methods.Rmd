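---
title: "Recovering PPM fish-tag transmissions from passive acoustic data: methods and design"
author: "podtag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering PPM fish-tag transmissions from passive acoustic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podtag)
```

## The problem

Coded acoustic fish tags (69 kHz V7/V9-class transmitters) identify an
individual animal by pulse position modulation: each transmission is a *code
packet* of 8 short ultrasonic pings spanning 3–3.5 s, and the identity is
carried entirely by the 7 inter-ping intervals. Purpose-built telemetry
receivers decode these packets in hardware. But two other instrument classes
record tag transmissions incidentally: cetacean click loggers (C-POD/F-POD
style), which store per-click summaries (time, frequency, cycle count,
amplitude) rather than audio, and towed hydrophone arrays, which record raw
broadband WAV. podtag turns both kinds of bycatch into tag identifications
in software, with no proprietary decoder hardware in the loop.

Two routes converge on the same decoder:

1. **Click-logger route** — filter the click log to candidate tag pings,
   search for packets anchored on the fixed sync interval, optionally rebuild
   each packet as audio from a single-ping template, re-detect it, and decode.
2. **Raw-audio route** — band-pass and envelope-detect pings directly in the
   recording, then find packets and decode.

## The packet model and the finder

A packet is modelled as 8 pings whose first gap is the *sync interval*
(0.280 s for the tags in view, tolerance ±5 ms by default), whose 6 further
gaps lie in an admissible data-interval window ([0.40, 0.60] s by default —
consistent with 8 pings spanning 3–3.5 s), and whose total span lies in
[3.0, 3.5] s. The pre-filter keeps only pings at 69–72 kHz (inclusive edges)
of at least 5 carrier cycles, mirroring the filtering a logger-side export
applies. Methods-style sources give the 69–72 kHz band while discussion of
the same tags quotes 69 ± 2 kHz; we default to 69–72 and expose both edges in
`finder_config()`.

`find_packets()` anchors on every ping pair whose gap matches the sync
interval and extends each anchor with the earliest subsequent admissible
ping. Two transient classes are skipped during extension
(`classify_multipath()`): *multipath echoes* — a weaker transient within 8 ms
of an accepted ping, the signature of a surface/bottom reflection — and
*strays*, anything else arriving before the minimum data interval. The
earliest-candidate rule is implemented as earliest-first depth-first search
with backtracking, i.e. it returns the lexicographically smallest admissible
completion of each anchor. On real streams backtracking essentially never
fires; its value is exactness: the result provably equals a brute-force
enumeration of all admissible 8-subsequences, which the test suite checks on
200 randomized streams. When accepted packets overlap, the earliest anchor
wins (ties broken by higher score), and later anchors inside an accepted span
are suppressed.

Quality is summarized by a 0–100 score. Hardware-free logger exports report a
score that is "high when the data is clean" without publishing a formula, so
the formula here is the package's own, chosen to reproduce that qualitative
behaviour with the simplest shape:

$$\mathrm{score} = \mathrm{clamp}\big(100 - w_s\,n_{\mathrm{stray}}
  - w_a\,\mathrm{CV}(A),\; 0,\; 100\big)$$

where $n_\mathrm{stray}$ counts every non-packet transient inside the packet
span (multipath included), $\mathrm{CV}(A)$ is the population coefficient of
variation of the 8 ping amplitudes, and the weights default to
$w_s = 10$ per stray and $w_a = 100$ per unit CV (both exposed in
`finder_config()`). The score is monotone: an extra stray or any
mean-preserving amplitude spread can only lower it.

## The PPM codec

Vendors' real codespaces are proprietary and rotate over time, so decoding
runs only against a user-supplied `ppm_codemap()`. A codemap fixes the sync
interval, the bin ladder `base_interval_s + symbol * step_s`, the number of
symbols, the modular checksum (`last symbol = sum of the others mod
n_symbols`) and the acceptance radius `max_residual_s`. Loading validates
`step_s > 2 * max_residual_s`, so two distinct valid interval vectors can
never lie within one acceptance radius of each other — a perturbation inside
the radius is corrected, anything larger is rejected as `off_bin`, and the
decoder never silently mis-decodes.

The shipped example codespace uses a 0.280 s sync, 6 data intervals of 8
symbols (0.455 s + 8 ms steps), checksum last, radius `step/3`; packets span
3.010–3.346 s and the ID space holds $8^5 = 32768$ tags. Tests invert the
codec over the entire space. One documented weakness is inherent to the
modular-sum checksum: swapping two id-carrying symbols preserves their sum,
so such a permutation re-validates and decodes to a different id. Real
systems guard against this with proprietary diagnostic patterns we do not
model; the package's packet-level timing constraints make such an event
require two independent interval errors of exactly complementary bin sizes.

## Audio detection and reconstruction

`detect_pings()` automates spectrogram screening: 4th-order Butterworth
band-pass at 69 ± 3 kHz (zero-phase, applied forwards-backwards; rejection an
octave off-center far exceeds 40 dB), analytic envelope by the FFT
half-spectrum construction, threshold at 10 % of the segment's maximum
envelope (or an absolute level), merging of super-threshold runs separated by
under 1 ms, and a 2 ms minimum ping duration. Input must be sampled at
≥ 140 kS/s or the 69 kHz carrier is simply not present; the validator
enforces this.

Two numerical conventions matter here:

* **Ping time = envelope-energy centroid of the run.** Tag pings are
  flat-topped (gated sinusoids with sub-millisecond ramps), so the literal
  envelope argmax over a noisy plateau is ill-posed — it can wander by
  milliseconds. The centroid equals the peak for symmetric pings, is robust
  to threshold choice, and is used identically by the simulator, the detector
  and the reconstructor, so recovered *intervals* are independent of the
  convention. Tests hold the detector to ≤ 0.5 ms timing error at SNR ≥ 10.
* **Frequency quantization.** The spectral-peak frequency of a
  few-millisecond transient has an honest resolution of a few hundred hertz,
  so the detector reports it quantized to 0.25 kHz. The simulated click
  logger likewise quantizes its logged frequency to 0.5 kHz (cycle-counting
  loggers are coarser still). This is also what makes the inclusive 69 kHz
  band edge usable in practice: an unquantized estimate of a 69.0 kHz carrier
  would fall below the edge half the time on measurement noise alone.

`reconstruct_packet_audio()` rebuilds a playable packet exactly in the
field-workflow layout: a baseline file of at least 5 s at 384 kHz, the first
ping's envelope peak at T = 1000 ms (the lead-in avoids start-of-file
playback artefacts), each later ping placed by its recovered interval,
rounded to the nearest sample. A 0.5 s tail pad avoids the mirror-image
artefact at the end of the file. The baseline defaults to silence; a white
Gaussian baseline at a configurable RMS is available where a noise floor is
wanted (a controllable stand-in for manually copied background noise).
Templates are peak-normalized to 0.9, and with the silence baseline the
output provably never clips. Round-trip fidelity (reconstruct, re-detect,
difference) is held to under 1 ms per interval by the tests, and in practice
is at the one-sample level.

## The simulator

`scenario()` + `gen_clickstream()` / `gen_audio()` replace field deployments
with a seeded, reproducible stand-in. It deliberately models only what the
detection problem needs:

* **Propagation** — the standard sonar-equation form
  `TL = k log10(r) + alpha r`, defaulting to spherical spreading (k = 20) and
  absorption `alpha = 0.025` dB/m, the right order of magnitude for ~69 kHz
  in seawater. TL is strictly increasing in range; the simulator needs a
  monotone, tunable stand-in rather than a calibrated channel model.
* **The tag** — source level 147 dB re 1 µPa @ 1 m (typical of V9-class
  coded tags), 5 ms pings (≈ 345 carrier cycles, far above the 5-cycle filter
  floor), one packet per `transmit_period_s` (10 s for range-test tags, 60 s
  for towed-array test tags) starting at a seeded uniform phase.
* **The receiver** — a pure amplitude threshold in received-level dB for the
  click-logger route (no SNR statistics); the audio route instead carries
  additive white Gaussian noise and leaves thresholding to the detector.
  Keeping the two noise models separate keeps the routes independently
  testable.
* **Nuisance processes** — optional per-ping multipath echoes (fixed
  delay/attenuation list), Poisson clutter clicks uniform in 20–160 kHz, and
  optional per-ping Gaussian received-level fading (`fading_sd_db`, default
  0). Fading, at 3 dB in the range experiment, is what turns detection
  against a threshold into a graded probability curve; without it the
  detection proportion is a step function of range.

What the simulator does **not** emulate — ray-traced propagation, Doppler
from fish movement, tide/weather covariates, site-to-site variability,
realistic clutter spectra (porpoise click trains can be temporally
structured, not Poisson) — bounds what passing tests show: they validate the
algorithmic pipeline under its stated model, not field detection ranges.
Absolute simulated ranges are therefore reported only as qualitative
contrasts (a low-threshold receiver profile out-ranges a high-threshold
logger profile), never as predictions.

Determinism: every generator is bit-identical under the same master seed;
clutter and audio-noise streams derive from it by fixed offsets so that
switching clutter on or off never perturbs the tag realization.

## Experiments

`run_accuracy_experiment()` is the in-silico analogue of lowering `n_tags`
(default 16) distinct tags one at a time within a few metres of a logger:
each tag's click stream is searched, the best-scoring packet reconstructed
at 384 kHz from a synthetic template, re-detected, and decoded; the report
counts correct, misidentified, undecodable and undetected tags. Under clean
defaults this yields 16/16 correct with zero misidentifications — the
software counterpart of a hardware-decoder cross-check in which no incorrect
identification occurs.

`run_range_experiment()` simulates 10-minute streams at each of
100–500 m (the classical paired range-test distances) for two receiver
profiles — detection thresholds of 85 dB ("receiver") and 100 dB ("pod") —
and reports the proportion of transmitted packets recovered *and correctly
decoded*. Decoding here consumes recovered intervals directly; the
reconstruction leg is already exercised end-to-end by the accuracy experiment
and the route-equivalence tests, and re-rendering hundreds of 384 kHz files
would add runtime, not coverage. The suite asserts the two qualitative
properties that survive desk scale: mean detection proportion is
non-increasing in range, and the high-threshold profile never out-ranges the
low-threshold one.

## Problem sizes and numerical choices

The default test and acceptance runs use: 30 s streams for the accuracy
experiment (≥ 2 complete packets per tag), 5 s audio scenarios at 192 kS/s
for the 50-seed route-equivalence sweep, 24 replicates × 7 ranges × 2
profiles of 600 s streams for the range curve, 200 random streams of ≤ 30
events for the finder-vs-brute-force comparison, and the full 32768-id
codespace for codec inversion. These sizes were chosen so the whole suite
exercises every claim at statistically meaningful depth while remaining
comfortable on a single CPU.

Window comparisons use inclusive boundaries with a 1e-9 s guard against
floating-point representation of decimal intervals; text exports round times
and intervals to 1 µs (lossless relative to millisecond-scale PPM bins) and
scores to 0.1. Degenerate inputs are defined, not accidental: empty click
files parse to empty streams, all-zero audio detects nothing, an empty packet
list exports a header-only file, and a scenario whose first transmission
falls beyond its duration generates pure background.

## Limitations

* Proprietary logger container formats are not parsed; the CSV schema stands
  in for a logger-side export step.
* The example codespace is illustrative. Decoding real tags requires the
  actual codemap for the deployment, supplied as JSON.
* The audio path is single-channel; towed-array bearing estimation and
  localisation are out of scope.
* Scores are comparable within a configuration, not calibrated across
  instruments.
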