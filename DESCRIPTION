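Package: trackserve
Title: In-Situ Query Engine for Indexed Genomic Track Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Queries BigWig, BigBed and Tabix-indexed tabular genomic files
    in situ: only the byte ranges needed to answer a genomic-range query are
    fetched (from local disk or from HTTP servers supporting range requests),
    accessed blocks are cached, and results are summarized to screen
    resolution through precomputed zoom levels or coverage-weighted binning.
    User-defined transformations over sets of tracks ("computed
    measurements") are aligned by interval overlap and evaluated lazily at
    query time. A measurement catalog is loaded from JSON configuration, and
    a REST API plus command-line interface expose catalog listing and data
    queries to genome-browser clients.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    curl,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Infrastructure, DataImport, Epigenetics, Visualization
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate:
    'conditions.R'
    'binary.R'
    'block-cache.R'
    'resource.R'
    'intervalframe.R'
    'bbi.R'
    'serialize.R'
    'tabix.R'
    'transform.R'
    'measurements.R'
    'query-engine.R'
    'server.R'
    'fixtures.R'
    'trackserve-package.R'
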