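Package: crisprpoly
Title: CRISPR-Cas9 Guide Design and Mutant Allele Tracking in Polyploid Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for knocking out multi-copy gene families in polyploid
    crops with CRISPR-Cas9: paralog discovery by seeded local alignment,
    design of guide RNAs conserved across all family members with
    seed-region SNP filtering and genome-wide off-target screening,
    mutant allele calling from amplicon and plasmid-clone sequences with
    left-aligned indel normalisation, decomposition of mixed Sanger-like
    traces into indel-size frequencies by non-negative least squares,
    multi-generation allele and transgene tracking with Mendelian
    segregation tests, and one-way ANOVA with Tukey post-hoc letters for
    phenotype tables. A seeded synthetic-data layer simulates tetraploid
    gene families, NHEJ edit outcomes, chromatograms, selfing pedigrees
    and phenotype measurements so the whole workflow can be exercised and
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    pracma,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
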