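Package: sonoflow
Title: Workflow Analysis of Routine Obstetric Ultrasound Scan Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative workflow analysis of full-length routine
    obstetric ultrasound examinations recorded as multimodal sessions: machine
    user-interface state extraction (freeze, image/clip save, displayed
    biometric measurements and thermal safety indices) from per-frame records
    or rendered screen rasters; event-anchored five-second clip partitioning
    and anatomy labelling; area-of-interest gaze fixation-episode detection
    with safety and biometry gaze audits; quaternion attitude-and-heading
    (AHRS) fusion of transducer inertial data into absolute orientation and
    world-frame linear acceleration; per-scan anatomy time-share statistics,
    normalized timelines, and inter-annotator confusion/agreement analysis;
    and sonographer-speech part-of-speech statistics.  A seeded synthetic
    scan-session generator emulates the multimodal recording setup (30 frames/s
    user-interface stream, 90 Hz gaze, 100 Hz inertial sensors, semi-Markov
    anatomy timeline, tagged speech) so the whole pipeline is testable without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
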