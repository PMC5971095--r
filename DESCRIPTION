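Package: graphovar
Title: Grapheme-Phoneme Analysis of Variability in Nonword Reading Aloud
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing why skilled adult readers produce variable
    pronunciations when reading nonwords aloud. Parses letter strings into
    graphemes (including discontinuous split digraphs such as O.E), tokenizes
    IPA transcriptions into phonemes, classifies each reading-aloud response
    as a standard or nonstandard graphemic parsing (phoneme count equal to
    grapheme count), tallies grapheme-phoneme assignments and classifies them
    as standard or nonstandard, and quantifies subject-level and item-level
    variability with Shannon entropy. Includes a synthetic reader-response
    generator with a ground-truth ledger for end-to-end validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
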