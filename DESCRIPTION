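Package: eparscan
Title: Detection and Evolutionary Analysis of Pseudoautosomal Region Extensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for screening SNP-array intensity data for Y chromosomes
    carrying an extended pseudoautosomal region (ePAR) and the reciprocal
    X-chromosome deletion, both products of non-allelic homologous
    recombination (NAHR) between a pseudoautosomal and an X-specific LTR6B
    element. Includes junction-sequence typing with crossover-interval
    inference, Y-haplogroup assignment on a SNP-labelled phylogeny,
    minimum-origin counting under irreversible parsimony, Y-STR (ASD) and
    SNP-accumulation TMRCA dating, NAHR rate estimation, X-linked
    Hardy-Weinberg testing, a Firth-penalized phenome-wide association scan,
    and a synthetic-data generator so every stage is testable with known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
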