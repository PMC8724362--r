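Package: sonocordance
Title: Pixel-Wise Concordance Analysis of Automated and Expert Heart Border Tracings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the agreement between automated ultrasound
    border tracings and expert reviewer tracings on B-mode images. Tracing
    overlays are extracted from annotated rasters, closed and filled into
    binary masks restricted to the sector scan area, and compared pixel by
    pixel to obtain confusion areas, Sorensen-Dice indices, and four-colour
    agreement renderings. A seeded phantom generator simulates biplane scan
    sets of a porcine heart across pre-arrest, arrest, and late-arrest
    physiologic states, including echogenic clot, rib-shadow acquisition
    failures, and configurable tracer error, so the full blinded screening,
    scoring, and per-reviewer aggregation workflow can be exercised and
    tested end to end without access to the original scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
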