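Package: zootrack
Title: Motion-Feature Video Tracking and Behavior Analysis for Captive Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for studying captive-animal behavior from fixed-camera
    video. A shared motion-feature extractor (double frame differencing of a
    frame triple, cleaned by morphological erosion and dilation, localized by
    a counting-box search) drives three applications: rat head-pose
    estimation and three-compartment visit analysis, monkey sensor-box
    localization and head-orientation estimation in an unevenly lit cage,
    and multi-camera fusion of a panda-bear trajectory with five-class
    stress-episode classification. Seeded synthetic scene renderers provide
    ground-truthed fixtures for every pipeline, so the methods are testable
    end-to-end without proprietary recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
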