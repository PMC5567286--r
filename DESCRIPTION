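Package: mirtrait
Title: MicroRNA Expression and Target-Site Polymorphism Association with
    Muscle Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline linking muscle-trait phenotypes in salmonid
    aquaculture populations to (a) small-RNA (microRNA) expression and
    (b) 3'UTR single-nucleotide polymorphisms that destroy or create
    microRNA seed-binding sites (MRESS). Covers adapter trimming and
    tolerant isomiR-collapsing quantification of small-RNA reads, exact
    count tests for differential expression between divergent family
    pools, a seed-rule target scanner with G:U wobble handling and
    nearest-neighbor duplex energies, allele-swap classification of
    target-site SNPs, pooled allele-frequency imbalance screening, and
    genotype/expression-phenotype association with rank-based inverse
    normal transformation. A synthetic-data generator with planted
    ground truth emulates the pooled family study design so every stage
    is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
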