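Package: beetleamp
Title: Context-Dependent Antimicrobial Peptide Expression Analysis for
    Burying Beetles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Curation of antimicrobial peptide (AMP) and lysozyme gene
    candidates from an assembled transcriptome, including an
    allele-versus-paralog adjudication rule based on synonymous and
    nonsynonymous nucleotide differences; RPKM quantification with
    Student's t-test and Benjamini-Hochberg corrected contrasts over a
    two-sex by three-context (no carcass, carcass, carcass plus larvae)
    design; and in-silico tryptic digestion with monoisotopic mass
    matching and sequence-coverage based presence calls for secreted
    effector proteins. Includes seeded synthetic-data generators for
    transcript families, count matrices, and secretome peptide mass
    lists with recorded ground truth, so the full pipeline is testable
    without raw sequencing or mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
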