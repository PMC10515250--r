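Package: bsamap
Title: Mapping-by-Sequencing of EMS Mutants by Bulked Segregant Allele-Frequency Scans
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of mapping-by-sequencing (MutMap-style)
    experiments that locate a recessive EMS-induced causal mutation from
    whole-genome sequencing of two phenotype-selected bulks. Provides a
    forward-genetics simulator (EMS variant sets, BC1F2 populations with
    Poisson-crossover meiosis, phenotype-selected bulks, pooled allele-depth
    sampling), two-sample VCF input/output with depth and substitution-class
    filters, per-variant bulk allele frequencies smoothed over a sliding
    window of SNPs with dual-threshold candidate-region calling, a miniature
    SNV consequence annotator against GFF3 gene models (codon and protein
    changes, exonic prioritization), recombinant fine-mapping over marker
    scaffolds with the Mendelian segregation chi-square test, and the
    downstream tabular summaries used in fruit-cuticle studies (differential
    expression threshold filters and category counts, fold changes, pooled
    Student's t tests, cell-wall sugar ratios and pectin esterification
    degrees).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
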