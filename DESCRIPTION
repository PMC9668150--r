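Package: clonechron
Title: Inferring Parameters of Cancer Evolution from Longitudinal Bulk Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Closed-form estimators of subclone net growth rates, exome
    passenger mutation rate, driver-mutation timing and time to clinical
    detectability for exponentially growing cancers (chronic lymphocytic
    leukemia in particular) observed by bulk sequencing at two or more
    longitudinal timepoints, under a multi-type branching-process model of
    tumor evolution. Includes corrections of observed mutation counts for
    subclonal passengers lost to variant-read filtering and for passengers
    reaching fixation after a driver event, a continuous-time Gillespie
    simulator of birth-death-mutation processes with driver introductions, a
    sequencing-read simulator, a sampling-based confidence-interval pipeline,
    and a ground-truth patient fixture generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
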