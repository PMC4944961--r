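Package: kennelscope
Title: Automated Behaviour Analysis of Kennel-Housed Quadrupeds from Depth Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the behaviour of a single quadruped (typically
    a shelter dog) confined in a pen, from side-mounted depth-camera video.
    The pipeline segments the animal from the calibrated pen planes, fits a
    seven-part skeleton by structured max-margin classification over an
    anatomically constrained candidate space, scores postures (stand, sit,
    lie, locomotion), projects barycentre trajectories onto the pen floor
    through a ground-plane homography, and summarises behaviour as an
    ethogram (durations, bouts, activity, distance, grid occupancy).
    Recurring movement patterns are discovered without a pre-set ethogram by
    global (Needleman-Wunsch) alignment of fixed-length windows of either
    floor coordinates or spectral skeleton-graph descriptors, followed by
    K-medoids clustering. A deterministic articulated-quadruped renderer
    generates annotated synthetic depth video so the full pipeline can be
    trained and validated without camera hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
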