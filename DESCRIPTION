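Package: rxsmooth
Title: Most Likely Drug-Combination Therapy from Noisy Prescription Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds daily drug-exposure series from longitudinal electronic
    prescription or dispensation records and estimates the most likely single-
    or multi-drug therapy over time with a two-pass sliding-window mode
    ("smooth") algorithm. Includes the persistence-threshold comparator
    traditionally used in pharmacoepidemiology, smoothing-impact statistics
    with a window-size simulation harness, a noncentral chi-square power
    calculation, a synthetic prescription-cohort generator with known ground
    truth, and CSV readers/writers plus a command-line interface binding the
    pieces into a pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, yaml, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
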