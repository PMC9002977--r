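Package: fallwatch
Title: Direction- and Severity-Aware Fall Detection from Wearable IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for activity recognition and fall detection from
    waist-worn inertial measurement unit (IMU) recordings that classifies
    falls jointly by direction (forward, backward, lateral) and severity
    (hard, soft) alongside four activities of daily living. Recordings in
    the SisFall plain-text format are parsed and converted to physical
    units, segmented into fixed 3-second windows centred on the peak of
    the acceleration magnitude (sliding non-overlapping windows for the
    long walking/jogging recordings), and minority classes are augmented
    by jittering, scaling and resampling. A small 1-D convolutional
    network is trained as a feature extractor with a temporary softmax
    head; the head is then replaced by a tuned gradient-boosted-tree
    classifier over the flattened convolutional features. Evaluation is
    by unweighted average recall with direction, severity and falls-only
    roll-ups. A synthetic IMU recording generator emulating the SisFall
    file layout and class structure makes the whole pipeline runnable
    without the real dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
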