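Package: aatrack
Title: Hippocampal Ensemble Analysis for Approach-Avoidance Conflict on a
    Predator-Guarded Linear Track
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing rodent approach-avoidance behavior and dorsal
    hippocampal electrophysiology on a linear track guarded by a threatening
    robot. Classifies behavioral events (hesitations, mid-track aborts,
    on-track pauses) from position tracking; segments the local field
    potential into theta and large-amplitude irregular activity states with
    cycle-by-cycle theta peak/trough identification and asymmetry metrics;
    detects sharp-wave ripples and population high-synchrony events; builds
    occupancy-normalized directional spatial tuning curves restricted to the
    descending phase of theta; and decodes spatial posteriors from ensemble
    spike counts with a one-step Bayesian decoder, including pre/post-attack
    cross-decoding of high-synchrony events and ascending/descending theta
    half-cycle decoding.  A synthetic-session generator produces complete
    labeled sessions (trajectory, spikes, multichannel LFP) so every stage of
    the pipeline can be exercised and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    data.table,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
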