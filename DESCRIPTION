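Package: ototoxkit
Title: Preclinical Ototoxicity Phenotyping from ABR and Acoustic Startle Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal preclinical ototoxicity studies
    in rodents. Converts auditory brainstem response (ABR) thresholds into
    per-ear clinically relevant threshold-shift responder calls, processes
    acoustic startle reflex trials into input/output functions and
    gap-prepulse-inhibition (GPIAS) ratios, classifies per-animal hyperacusis
    and tinnitus phenotypes against baseline with repeated-testing-aware ANOVA
    contrasts, and performs exact 2x2 incidence inference (two-sided Fisher
    test and Koopman asymptotic-score relative-risk intervals). Ships a
    synthetic-cohort generator that emulates a three-group tobramycin/ebselen
    dosing study so every stage is testable without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    pracma,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
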