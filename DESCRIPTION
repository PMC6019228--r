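Package: miniscan
Title: Selection Signatures and Body-Size Genetics of Miniature Ponies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for dissecting the genetics of extreme
    body-size reduction in small horse breeds from whole-genome variant data.
    Implements PLINK-style detection of runs of homozygosity (ROH) and their
    intersection across individuals, sliding-window Hudson Fst scans between a
    small case group and a pooled control panel, screening of variants inside
    shared ROH regions by predicted effect and case-exclusive homozygous
    genotype patterns, read-depth log2-ratio copy-number calling with
    multi-pairing CNVR intersection, dating of selection from ROH length via
    the 1/(2c) relation, and multi-locus additive genotype-trait models
    including a four-locus size-ceiling classifier. A synthetic-population
    generator with planted autozygous tracts, divergent loci, causal trait
    loci and copy-number events makes the whole pipeline testable end to end
    without sequence data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
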