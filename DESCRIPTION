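Package: genelossr
Title: Gene Loss Dynamics in Comparative Genomics: Network Simulation,
    Copy-Number Trends and Synteny-Anchored Loss Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying gene loss as an evolutionary force in a
    lineage of related genomes. Implements a Wagner-style Boolean threshold
    gene-regulatory-network simulator that compares gene deletion against
    gene duplication as sources of novel stable expression states; a
    copy-number trend scanner that regresses orthologous-group gene counts
    on phylogenetic distance to the last common ancestor and flags
    contracting or expanding groups as Tukey-fence outliers; and a
    synteny-anchored locus classifier that labels each anchor locus in each
    target species as retained, decayed, deleted or non-informative using a
    self-contained six-frame translated local-alignment search with
    Karlin-Altschul E-values. A synthetic-data module generates count
    matrices, species trees and toy syntenic genomes with planted loss
    events so the whole analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods,
    Rcpp,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
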