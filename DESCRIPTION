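Package: wgr
Title: Whole-Genome Reconstruction of Preimplantation Embryos from Parental
    Sequencing and Sparse Biopsy Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the inherited genome of in-vitro-fertilized embryos
    from whole-genome sequencing of the parents plus sparse, noisy SNP-array
    genotypes of embryo biopsies. Implements parental-support phasing of
    parental heterozygous sites from sibling-embryo co-inheritance, a
    four-state hidden Markov model over transmitted parental haplotypes with
    an allele-dropout-aware emission model and a Haldane transition kernel,
    meiotic recombination breakpoint calling, dense genotype prediction,
    polygenic risk scoring with principal-component-based centering and
    standardization, carrier-stratified integration of monogenic and
    polygenic risk, and simulation of the polygenic-score distribution of a
    couple's potential embryos. Ships a ground-truthed synthetic family
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
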