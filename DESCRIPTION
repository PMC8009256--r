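Package: zapgaze
Title: Microsaccade Analysis for Continuous Visual Search Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing saccades and microsaccades in high-rate gaze
    recordings from continuous visual search ("zapping") paradigms, in which a
    new small face target appears the moment gaze reaches the previous one.
    Provides a noise-adaptive velocity-threshold event detector (elliptic
    threshold at a configurable multiple of a median-based noise estimate,
    minimum-duration criterion, 1-degree saccade/microsaccade split), peri-event
    alignment of events to trial and saccade anchors with rate histograms and
    count distributions, Procrustes mapping of movement endpoints onto a
    template face with disk-smoothed endpoint-frequency maps, maximal-run
    statistics over correct and microsaccade-free trials, and a synthetic
    gaze-trace simulator with ground-truth event logs that emulates the task
    structure (main-sequence saccade kinematics, post-saccadic microsaccades,
    landmark-anchored endpoint scatter) so the whole pipeline is testable
    without recorded eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan
Config/testthat/edition: 3
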