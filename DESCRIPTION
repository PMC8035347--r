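Package: fish3d
Title: Automated 3D Scoring of Break-Apart FISH Signals in Confocal Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores fluorescence in situ hybridization (FISH) break-apart
    assays from multi-channel confocal z-stacks. Segments individual cell
    nuclei in the DAPI channel by ellipse template matching, detects FITC and
    TRITC gene signals as 3D intensity maxima, pairs opposite-channel signals
    by ranked 3D distance with non-repetitive greedy selection, classifies
    per-nucleus signal patterns (normal, multiple copy, typical and
    non-typical break-apart, other) and aggregates them into a case-level
    positive/negative diagnosis. Includes a synthetic z-stack generator with
    ground truth, calibrated TIFF stack input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
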