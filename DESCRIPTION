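Package: pollenscan
Title: Crossover and Segregation-Distortion Analysis of Single-Pollen
    Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of haploid gamete (single pollen nucleus) genotype
    panels on a genetic map: quality control of whole-genome-amplified
    allele calls, parental-origin phasing, meiotic crossover detection and
    per-arm counting, per-interval recombination frequency, chi-square
    scanning for transmission-ratio (segregation) distortion contrasted
    between a pollen population and a sexual progeny, and simple-matching /
    neighbor-joining diversity analysis of gamete populations. Includes a
    meiosis simulator (Haldane or Kosambi mapping function, gametic and
    zygotic selection, amplification dropout) that generates gamete and
    progeny populations with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
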