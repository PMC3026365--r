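Package: assocnet
Title: BLAST Association Networks for Phylogenetic Sequence Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds bipartite association networks from collective BLASTN
    results to screen environmental sequence collections (such as 16S rRNA
    phylotype surveys) for hits that are associated with multiple supplied
    queries, then carries the selected sequences through multiple alignment,
    distance estimation and neighbor-joining tree inference. Includes parsers
    for NCBI BLAST XML and tabular reports, FASTA/GenBank/raw sequence import,
    GraphML/PHYLIP/Newick export, a deterministic synthetic-fixture generator
    with planted association structure, a file-backed job queue and permanent
    parameter provenance for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
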