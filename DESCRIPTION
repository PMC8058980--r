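Package: codonopt
Title: Zoned Codon Optimization and Transgene Copy-Number Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for designing heterologous coding sequences for
    Rhodosporidium toruloides and similar hosts. Builds codon usage tables
    from coding-sequence sets, computes codon adaptation index (CAI), RSCU
    and usage-distance statistics, and implements two design strategies: a
    high-CAI (HC) rule that always uses the organism's preferred codon, and
    a zoned expression cassette optimization (ECO) that places a
    translational-start-consensus codon at position 2, rare codons at
    positions 3-10 to weaken 5' mRNA structure, preferred codons at
    positions 11-45 and over the last 50 codons, and usage-matched codons in
    between. Also includes a read-depth transgene copy-number genotyper for
    cassettes integrated on an augmented reference, a binned depth
    simulator, and a copy-number versus product-titer regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
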