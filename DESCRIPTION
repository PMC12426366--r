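Package: camtrapeval
Title: Evaluation of Multiclass Wildlife Detectors on Camera-Trap Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate custom multiclass object detectors applied to
    camera-trap images, working entirely from tabular detector output and
    verified annotations rather than from the images themselves. Implements
    empty-image filtering metrics (image-level sensitivity and specificity
    across confidence-score thresholds, agreement between two detectors,
    and review-subset planning), image-level species-classification metrics
    (per-class precision, recall and F1 over a threshold sweep,
    threshold-averaged and macro-averaged summaries, and regressions of
    performance on training-set size), ecological concordance metrics
    (site-level species richness regressions and per-image animal-count
    bias models including a Poisson GLM), and a synthetic camera-trap study
    generator with a parametric detector-error model whose closed-form
    expected metrics support end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
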