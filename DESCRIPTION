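Package: fairbag
Title: FAIR Data Packaging, Identification, and Provenance for Genomic Workflows
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for making large genomic analyses Findable, Accessible,
    Interoperable, and Reusable (FAIR). Implements the Big Data Bag (BDBag)
    exchange format -- BagIt bags extended with remote file references
    (fetch.txt) and an embedded Research Object manifest -- together with
    checksum-bound minimal viable identifiers (Minids) backed by a local
    registry, recursive materialization of "bags of bags", conversion of
    ENCODE-portal metadata tables into per-tissue holey bags with recorded
    queries, pipeline fan-out planning and dataset bookkeeping, a
    16-criterion FAIRness rubric, and intersection of DNase footprints with
    motif hits to call candidate transcription-factor binding sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    utils,
    stats,
    tools,
    digest,
    jsonlite,
    withr,
    zip,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: DataImport, Infrastructure, ReproducibleResearch
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bag-create.R'
    'bag-io.R'
    'bag-validate.R'
    'cli.R'
    'fixtures.R'
    'intersect.R'
    'manifest.R'
    'materialize.R'
    'registry.R'
    'research-object.R'
    'rubric.R'
    'utils.R'
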