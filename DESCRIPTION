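Package: cdsbattery
Title: Acoustic-Lexical Profiling of Child-Directed Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement battery for child-directed speech (CDS) in
    caregiver-child play sessions: lexical diversity (types, tokens, TTR,
    moving-average TTR), phono-lexical statistics against a pronouncing
    lexicon (positional biphone phonotactic probability, phonological
    neighborhood density, word length, word frequency), and acoustic
    hyperarticulation measures (Lobanov-normalized vowel space area, vowel
    dispersion, phone duration, Mel-spectral coarticulation distance).
    Includes nonword-repetition scoring with a real-word articulatory
    control, mixed-model and regression machinery with a residualization
    procedure for disentangling collinear input predictors, and a synthetic
    corpus generator with known ground truth for validating every stage of
    the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
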