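Package: daeqtl
Title: Differential Allele Expression QTL Analysis for Reciprocal F1 Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cis-acting regulatory variation and genomic imprinting
    from allele-specific RNA-Seq read counts in reciprocal F1 hybrid crosses.
    Per-SNV allele counts obtained by mapping against both parental reference
    genomes are averaged to cancel reference mapping bias, aggregated to
    gene level, and tested for allelic imbalance with an exact binomial test
    and Benjamini-Hochberg FDR control. Genes significant with the same
    strain direction in both reciprocal crosses are called strain-specific
    DAE QTLs; genes whose imbalance tracks parental origin are called
    imprinted. Includes tissue-specificity comparison, gene-set overlap
    enrichment against candidate-gene and cis-eQTL lists, orthogonal
    validation statistics (gDNA-normalized Sanger allele fractions, qPCR
    delta-Ct fold changes), and a synthetic-data generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
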