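Package: circscape
Title: Characterization of Plant Circular RNAs from Back-Splice Junction Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for characterizing plant circular RNAs
    (circRNAs) from back-splice junction call tables, as produced by
    detection tools such as CIRIquant and find_circ. Provides consensus
    filtering of calls from two callers, classification into exonic,
    intronic, intergenic and antisense types against a gene annotation,
    junction-sequence and k-mer-profile conservation scoring, comparison
    of flanking-intron repeat content and weighted DNA methylation against
    sampled linear-gene backgrounds, RPB/FPKM quantification with exact
    negative-binomial differential expression, miRNA target-site
    prediction with an expectation score, and assembly of a
    circRNA-miRNA-mRNA sponge network. Includes a seeded synthetic-data
    generator that plants known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
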