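Package: mitocomp
Title: Comparative Analysis of Annotated Animal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative mitogenomics of insects and other
    invertebrates. Reads annotated mitochondrial genomes (GenBank flat
    files or FASTA plus feature tables), computes base composition and
    AT/GC strand skews, relative synonymous codon usage (RSCU) and
    start/stop codon classification under the invertebrate mitochondrial
    genetic code, scans gene junctions for conserved overlaps and
    intergenic spacers, locates control regions, compares signed gene
    orders against the ancestral insect arrangement, estimates pairwise
    Ka/Ks by the Nei-Gojobori (1986) pathway method and Tamura-Nei (1993)
    distances with transition/transversion saturation tables, and prepares
    concatenated protein-coding supermatrices with partition definitions
    for external phylogenetic inference. A seeded synthetic-mitogenome
    generator with machine-checkable ground truth supports end-to-end
    testing without any sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
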