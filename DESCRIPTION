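Package: lcdtrack
Title: Lamina Cribrosa Depth Morphometry and Longitudinal Glaucoma
    Progression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based measurement of lamina cribrosa depth (LCD) from
    annotated optical coherence tomography B-scans (maximum perpendicular
    distance from anterior lamina cribrosa landmarks to the Bruch's membrane
    opening reference line), per-subject annualized rates of change of LCD,
    circumpapillary retinal nerve fiber layer (RNFL) thickness and intraocular
    pressure after glaucoma surgery, an aging-adjusted RNFL progression
    classifier, and cohort-level inference: random-intercept linear
    mixed-effects trends, exact Wilcoxon signed-rank and Mann-Whitney tests,
    and univariate plus stepwise multivariate regression. Includes a seedable
    synthetic-cohort and synthetic-eye generator with known ground truth so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    readxl,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
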