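Package: pentrack
Title: Tracking-by-Detection and Single-Line Counting for Animal Pen Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A detection-agnostic multi-object tracking and counting toolkit
    for fixed-camera livestock pen surveillance. Links per-frame bounding-box
    detections (MOT-Challenge format) into identity-preserving trajectories
    with a constant-velocity Kalman filter, Mahalanobis-gated appearance
    cascade matching and IoU fallback matching, and track lifecycle
    management; counts animals crossing a virtual line with a two-set
    (touched / detached) state machine; evaluates detection and tracking
    output with precision, recall, average precision, average overlap rate,
    and mean centre-location error; and ships a synthetic pen-scene
    simulator so the whole pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
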