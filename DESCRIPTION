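Package: hostdrift
Title: Within-Host Genome Stability Analysis for Bacterial Isolates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the genomic stability of a bacterial strain
    re-isolated from host gut samples against its multi-replicon reference
    genome: a seeded synthetic-genome and paired-end read simulator, a k-mer
    seed-and-extend local nucleotide aligner with read pseudo-mapping and
    fragment-based average nucleotide identity (ANI), SNP identification with
    quality/depth/repeat filtering and codon-level effect classification
    (synonymous, non-synonymous, nonsense, intergenic), core/accessory
    pan-genome delineation, coverage-based plasmid presence calling with the
    plasmid loss ratio (PLR) statistic, acquired-fragment (HGT) detection, and
    cohort-level ANI descendant screening with mutation-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
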