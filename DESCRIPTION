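Package: vocalrange
Title: Vibrating-String Model of Vocal Fold Fundamental Frequency Range
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward and inverse computations for a vibrating-string model of
    vocal fold vibration across mammals. Predicts achievable fundamental
    frequency range (in octaves) from vocal fold elongation capacity (L2/L1)
    and the exponent B of an exponential tissue stress-strain law, inverts
    the model for the stiffness or elongation required to reach a target
    range, fits allometric power laws (vocal fold length and f0 bounds
    versus body mass) and the B-versus-length regression on a packaged
    cross-species trait table, and generates synthetic species tables with
    known ground truth for parameter-recovery experiments. Includes a small
    command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
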