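Package: erquant
Title: Quantitative Estrogen-Receptor Immunohistochemistry Scoring
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative scoring of estrogen-receptor (ER)
    immunohistochemistry in brightfield photomicrographs of
    DAB-stained, hematoxylin-counterstained breast-cancer tissue.
    Implements Beer-Lambert optical-density calibration, H-DAB color
    deconvolution, stereological grid sampling of nuclei, a 0.1-OD
    nuclear positivity cutoff, a quantitative ER score on a 0-10 scale,
    and an Allred-compatible mapping that detects discordant (3+0, 4+0,
    5+0) cases invisible to semi-quantitative reading. Includes a
    forward-model synthetic slide generator with known ground truth,
    cohort-level statistics (descriptives, Pearson correlation, Cohen's
    d), and command-line entry points for scoring, cohort analysis and
    synthesis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
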