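Package: WGDpaint
Title: Reconstructing Recurrent Whole-Genome Duplications and Descending
    Dysploidy from Comparative Genomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully tested re-implementation of a comparative
    genomics workflow for reconstructing the polyploid history of grass
    genomes. The package filters all-vs-all similarity hits into reciprocal
    best hits, estimates synonymous divergence (Ks) for homolog pairs with a
    protein-guided codon alignment and the Nei-Gojobori (1986) estimator,
    dates whole-genome duplications by expectation-maximization fitting of
    Gaussian mixtures to Ks distributions and a molecular clock, chains
    collinear homolog pairs into syntenic blocks with depth-ratio inference,
    and paints genes with ancestral-chromosome origins by bitscore-weighted
    bootstrap to call nested chromosome insertions, fusions and
    translocations. A genome-history simulator generates multi-species gene
    sets descended from a 12-chromosome grass ancestor so that every stage
    is verifiable against scripted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ComparativeGenomics, Phylogenetics, WholeGenome, Alignment
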