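Package: huculnet
Title: Pedigree Efficiency Statistics and Neural Ranking Models for Hucul Performance Championships
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing Hucul horse performance-championship records:
    championship scoring arithmetic, pedigree-line start-efficiency
    coefficients (SR/ASR), fuzzy strong/medium/weak labelling of finishing
    positions, leakage-safe categorical feature encoding, feedforward tanh
    networks trained from scratch with the Levenberg-Marquardt method,
    tolerance-banded position-prediction accuracy and group-classification
    efficiency under repeated cross-validation, and a synthetic championship
    generator with planted, recoverable ability structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    stats,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
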