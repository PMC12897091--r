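Package: msquant
Title: Quantitative Microsatellite Instability Scoring from Aligned Reads
Version: 0.1.0
Authors@R:
    person("msquant", "developers", email = "msquant@example.org",
           role = c("aut", "cre"))
Description: A transparent, panel-adaptable workflow for determining
    microsatellite instability (MSI) status from aligned tumor sequencing
    reads. Reads in SAM format are filtered by mapping quality and alignment
    flags, assigned to microsatellite loci from a user-supplied panel, and
    the local reference sequence is reconstructed from CIGAR strings and MD
    tags without an external FASTA. Insertions, deletions and substitutions
    inside each repeat tract are counted per read, summarised into two
    sample-level instability metrics (percent mutated reads and percent
    total mutations), and classification cutoffs are calibrated by ROC
    analysis with the Youden index. Includes concordance statistics against
    reference assays, the classical PCR marker-panel rule, and a seeded
    synthetic read generator producing internally consistent SEQ, CIGAR, MD
    and NM fields for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
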