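Package: hearscreen
Title: Headless Hearing Screening Simulator with Virtual Patients
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A scriptable simulation engine for teaching hearing-screening
    technique. Provides virtual standardized patients with per-ear audiogram,
    tympanometry and otoscopy ground truth and randomized demographics;
    simulated otoscopy, tympanometry and fixed-level pure-tone screening with
    a psychometric (guess/lapse-adjusted logistic) response model; automatic
    grading of technician notes against ground truth; protocol-compliance
    auditing of the timestamped session event log; markdown and JSON debrief
    reports; and an append-only session store supporting per-student history
    and cohort summaries. Sessions can be driven headlessly from scripted
    action files for reproducible training and assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
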