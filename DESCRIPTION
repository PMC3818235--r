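Package: ubdvmr
Title: Visceromotor Response Scoring and Simulation for Urinary Bladder
    Distension Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the visceromotor response (VMR) evoked by
    graded urinary bladder distension (UBD) in lightly anesthetized rodents.
    Provides the standard epoch-based scoring of abdominal electromyograms
    (per-event background subtraction, rectification, trapezoidal integration,
    session-minimum normalization, triplicate averaging), constructors for the
    common distension/anesthesia/body-temperature protocols, a synthetic EMG
    generator whose evoked envelope grades with distension pressure and encodes
    anesthesia-drift, hypothermic suppression and cooling hysteresis, balanced
    fixed-effects one- and two-way ANOVA with Bonferroni post-tests, and a
    Western-blot densitometry pipeline (phospho/total ERK ratios normalized to
    a normothermic control group). Includes replicated simulation studies for
    power and type-I behaviour of the full pipeline and a small command-line
    interface for end-to-end reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
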