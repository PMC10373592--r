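Package: crispamp
Title: Amplicon-Based Quantification of Multi-Allelic CRISPR Editing in Polyploids
Version: 0.1.0
Authors@R:
    person("Dana", "Moreno", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for molecular characterization of CRISPR/Cas9 editing outcomes
    at a multi-copy amplicon locus in a polyploid genome: locus modelling with
    in-silico PCR and CAPS restriction digestion, indicator-pair read filtering
    with alignment-based indel calling and frameshift classification, tracking of
    native target-site variants, SNP-profile allele resolution with detection of
    homology-directed repair signatures and conversion-tract bounding, capillary
    electrophoresis peak-table analysis, and summary statistics (editing
    efficiencies, one-way ANOVA with Tukey HSD compact letter display). Includes
    a ground-truthed synthetic amplicon read generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
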