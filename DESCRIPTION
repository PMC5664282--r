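Package: eggscreen
Title: Validation and Application of Qualitative Antimicrobial Residue
    Screening in Eggs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical validation calculus for qualitative and
    semiquantitative LC-MS/MS multiresidue screening of antimicrobial
    residues in eggs: noise-derived positivity thresholds (T-value),
    cut-off factors (Fc), signal-to-noise limits of detection, detection
    capability (CCbeta) verdicts, screening sensitivity and selectivity
    interference checks.  Includes a two-transition MRM identification
    and maximum-residue-limit compliance classifier, a packaged
    45-analyte panel with levels of interest derived from regulatory
    limits, and synthetic generators for validation response tables and
    egg residue depletion series so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
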