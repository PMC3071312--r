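Package: evotol
Title: Quantitative Analysis of Microbial Solvent-Tolerance Evolution Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of experimental evolution
    studies of solvent tolerance in bacteria: maximum specific growth rate
    estimation from microplate OD600 time series, relative-fitness and
    inhibition statistics, multiplicative-model epistasis decomposition of
    combination-mutant fitness, mutation catalogs and allele-trajectory
    ordering, resequencing variant triage (quality/frequency filters,
    coverage-gap tabulation, homopolymer read filtering), spot-level
    microarray preprocessing and moderated-t differential expression,
    Network Component Analysis of transcription-factor activities with a
    TF-subset consensus procedure, and mechanistic (MAK2) qPCR
    quantification. Includes seeded synthetic-data generators emulating
    each input so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
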