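Package: nestwin
Title: Climate-Window Inference for Breeding Phenology and Reproductive
    Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links daily montane climate station records (SNOTEL-style
    snowpack, temperature, precipitation and soil series) to avian
    nest-record responses through an exhaustive absolute sliding-window
    search scored by AICc against an intercept-only null, a year-block
    randomization gate against false positives (P-rand), Gaussian and
    mean-parameterized generalized-Poisson response models, and a staged
    final-model-selection protocol (likelihood-ratio screening,
    similar-variable deduplication, collinearity pruning and all-subsets
    AICc competition).  Ships a synthetic-data generator with known
    ground truth so the whole pipeline is testable without any field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB
Config/testthat/edition: 3
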