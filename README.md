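# podtag

Recover coded acoustic fish-tag transmissions from passive acoustic
monitoring bycatch — in software, end to end.

## Why

Acoustic fish tags (69 kHz V7/V9-class transmitters) broadcast their
identity as a *code packet*: 8 ultrasonic pings spanning 3–3.5 s whose 7
inter-ping intervals carry the tag ID by pulse position modulation (PPM).
Cetacean click loggers (C-POD/F-POD style) and towed hydrophone arrays
record these transmissions incidentally, but neither can decode them —
loggers store only per-click summaries (time, frequency, cycle count,
amplitude) and decoding normally requires proprietary receiver hardware.

podtag closes that gap for anyone running passive acoustic monitoring who
wants fish-telemetry detections out of instruments that were never meant to
provide them:

* **Click-logger route** — filter a click-event table to candidate tag pings
  (69–72 kHz, ≥ 5 cycles), search for packets anchored on the fixed 0.280 s
  sync interval with multipath tolerance and quality scoring, optionally
  rebuild each packet as a playable 384 kHz WAV (first ping at T = 1000 ms in
  a ≥ 5 s file), and decode.
* **Raw-audio route** — detect pings directly in any WAV sampled at
  ≥ 140 kS/s (band-pass at 69 ± 3 kHz, analytic-envelope thresholding), then
  find packets and decode.
* **Software PPM codec** — a configurable codespace (sync interval, interval
  bin ladder, modular checksum, acceptance radius) loaded from JSON; decoding
  either returns the encoded ID or a structured rejection
  (`bad_sync` / `off_bin` / `bad_checksum`), never a silent mis-decode.
* **Seeded simulator** — sonar-equation propagation
  (`TL = k log10 r + alpha r`), multipath echoes, Poisson clutter and level
  fading drive reproducible accuracy and detection-range experiments.

The score attached to each packet is
`clamp(100 − 10·n_stray − 100·CV(amplitudes), 0, 100)`: high for clean
packets, falling with stray/multipath transients in the packet span and with
amplitude spread.

## Worked example

Simulate a tag drifting clutter into a click logger, recover the packet and
decode it:

```r
library(podtag)

scen <- scenario(tag_id = 1723, duration_s = 30, range_m = 5,
                 clutter_rate_hz = 0.5, seed = 42)
sim <- gen_clickstream(scen)
sim$stream
#> <click_stream 'sim-tag1723-seed42' [synthetic]: 36 events over 30.000 s>

packets <- find_packets(sim$stream)
packets[[1]]
#> <code_packet t0=9.148060 s, intervals [0.280, 0.455, 0.479, 0.471, 0.511,
#>  0.479, 0.511] s, score 100.0>

decode_intervals(packets[[1]]$intervals_s)
#> <decode: tag 1723>
```

The stream held 36 logged clicks (3 × 8 tag pings plus clutter); the finder
anchored on the 0.280 s sync gap, assembled a full 8-ping packet with a
perfect score of 100 (no strays inside the span, equal amplitudes), and the
decoder quantized the six data intervals back to the transmitted identity.

The same works from raw audio (`detect_pings()` on a WAV at ≥ 140 kS/s), and
the accuracy experiment chains every stage — click simulation, packet
search, 384 kHz waveform reconstruction, re-detection, decoding:

```r
run_accuracy_experiment(n_tags = 3, seed = 7)
#> <accuracy_report: 3/3 correct, 0 misidentified, 0 no_match, 0 undetected>
```

A command-line wrapper over the same functions lives at `inst/cli/podtag`
(subcommands `detect-audio`, `find-packets`, `reconstruct`, `decode`,
`pipeline`, `simulate`, `experiment`); an example codemap is in
`inst/extdata/example_codemap.json`.

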