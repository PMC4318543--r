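Package: aphidtrack
Title: Automated Video-Tracking Phenotyping of Aphid Probing Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts centre-point trajectories of aphids confined to leaf-disc
    arenas into plant-penetration ("probe") events with a velocity-threshold
    state machine with hysteresis, derives the resistance-indicative response
    variables used in plant-aphid screening (probe counts and durations by
    category, time not moving, distance moved), matches automated against
    manually annotated probe streams for validation, and estimates the sample
    size needed to detect a plant-line effect by truncated-normal Monte Carlo
    simulation with Bonferroni-combined Student's t-tests. Includes a
    ground-truthed synthetic-data generator (behaviour schedules, trajectory
    rendering, greyscale frame rendering) and a minimal grey-threshold blob
    tracker that closes the loop from video frames back to trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
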