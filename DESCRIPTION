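Package: ncf1cnv
Title: Copy-Number Calling and Expression Dissection for NCF1 and Its Pseudogenes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integer copy-number genotyping of the NCF1 locus at 7q11.23 from
    paralog-specific-variant (PSV) allele fractions measured by pyrosequencing.
    Inverts the two PSV read-outs (the exon-2 GT/GTGT indel and the exon-9 A/G
    substitution) to integer copy numbers of NCF1B, NCF1 and NCF1C by
    constrained grid search, classifies measured pseudogene:NCF1 ratios into
    ratio classes, deduces per-chromosome duplicon haplotypes across pedigrees
    and checks Mendelian transmission, summarises and compares populations,
    dissects cDNA allele fractions into per-paralog transcript contributions,
    and performs standard-curve RT-qPCR relative quantification. Includes a
    seeded synthetic-data generator (haplotype pools, gene dropping, noisy
    pyrograms, expression and Ct tables) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
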