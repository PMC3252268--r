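Package: arescore
Title: Numerical Assessment of AU-Rich Elements in 3'UTR Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores AU-rich elements (AREs) in 3'UTR or arbitrary nucleotide
    sequences by counting AUUUA pentamers and rewarding pentamer proximity and
    surrounding AU-rich context (AU-blocks). Includes composition-matched and
    concatemer null-sequence generators, enrichment statistics (chi-squared,
    Fisher's exact test, phi coefficient), ROC/AUC discrimination of labile
    versus stable mRNAs, tie-aware rank correlation with censored half-lives,
    censored half-life fitting from transcription-shutoff decay time courses,
    a synthetic-transcriptome generator with planted AREs, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    optparse,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
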