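Package: ribote
Title: Ribosome Profiling Quality Control, Translational Efficiency, and
    Differential Translation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A transcriptome-space ribosome profiling toolkit: footprint
    library quality control (read-length distribution, P-site reading-frame
    periodicity, metagene profiles, replicate reproducibility), RPKM and
    translational-efficiency (TE) quantification, z-score based calling of
    differentially translated genes between two conditions, and 5' UTR
    feature analysis (length, GC content, terminal oligopyrimidine tracts,
    upstream open reading frames). Includes a seeded synthetic-data
    generator that emulates paired footprint and total-mRNA libraries with
    planted translational effects and UTR features, so every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
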