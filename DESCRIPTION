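Package: podtag
Title: Find, Reconstruct and Decode Acoustic Fish-Tag Code Packets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for recovering pulse-position-modulated (PPM) acoustic
    fish-tag transmissions from third-party passive acoustic monitoring data.
    Filters click-event logs exported from cetacean click loggers (C-POD /
    F-POD style) down to candidate 69 kHz tag pings, searches them for 8-ping
    code packets anchored on the fixed sync interval with multipath tolerance
    and quality scoring, detects tag pings directly in high-rate WAV audio,
    rebuilds playable code-packet waveforms from recovered ping intervals, and
    decodes interval sequences to tag identities against a user-supplied PPM
    codemap with checksum validation. A seeded propagation simulator (log-law
    spreading plus absorption, multipath echoes, Poisson clutter) generates
    synthetic click streams and audio for accuracy and detection-range
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
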