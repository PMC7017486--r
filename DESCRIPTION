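Package: graphsv
Title: Structural-Variant Genotyping on Pangenome Variation Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for genotyping structural variants (deletions,
    insertions, inversions) with a pangenome variation graph. Builds a
    bidirected sequence graph from a reference FASTA and an SV catalog in VCF,
    detects snarls (sites of variation bounded by a pair of node sides), maps
    paired-end short reads to the graph with a seed-and-extend aligner,
    summarises read support per node base and per edge in a coverage ("pack")
    index, genotypes each top-level reference snarl from the relative support
    of its candidate haplotype traversals, and benchmarks SV call sets against
    a truth set using reciprocal-overlap matching for deletions/inversions and
    Smith-Waterman sequence matching for insertions. A simulation module
    generates synthetic genomes, SV catalogs with realistic size distributions,
    breakpoint-perturbed catalogs, and paired-end reads at a grid of depths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
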