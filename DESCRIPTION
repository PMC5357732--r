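Package: scnBoundary
Title: Small-RNA and Heterochromatin Boundary Profiling at Internal
    Eliminated Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the precision of heterochromatin and
    small-RNA (scnRNA) boundaries at internal eliminated sequences (IESs)
    in ciliate germline genomes. Represents a segmented MIC genome
    (MDS / type-A IES / type-B IES), filters 26-32 nt scnRNA reads, builds
    strand-aware binned locus profiles and boundary-anchored meta-profiles
    for small-RNA-seq and input-normalized ChIP-seq, and computes the
    per-boundary broken boundary index (BBI) with ranking, distribution
    summaries and top-N heatmap matrices. Includes a seeded synthetic-data
    generator that emulates wild-type and boundary-mutant scnRNA and ChIP
    libraries so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
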