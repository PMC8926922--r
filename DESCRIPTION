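Package: kmerpanel
Title: k-mer Presence/Absence Population Genomics and Association Mapping
Version: 0.1.0
Authors@R:
    person("kmerpanel", "developers", email = "kmerpanel@example.org",
           role = c("aut", "cre"))
Description: Builds canonical k-mer presence/absence matrices across a panel
    of diploid accessions and runs the downstream population-genomic stack on
    them: identity-by-state redundancy and residual-heterozygosity quality
    control, UPGMA bootstrap phylogenies, principal component analysis,
    three-set Venn partitions of lineage k-mer space, sliding-window
    Weir-Cockerham fixation index, linkage-disequilibrium decay,
    correlation-prefiltered k-mer association mapping with a nested-model
    likelihood-ratio test and effective-variant Bonferroni correction,
    longest-hit anchoring of de novo assemblies, and lineage-specific k-mer
    painting of hexaploid-like chromosomes. A synthetic-panel generator with
    a full ground-truth ledger makes every stage testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
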