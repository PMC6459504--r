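---
title: "Methods: FAIR packaging, identification, and provenance in fairbag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FAIR packaging, identification, and provenance in fairbag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairbag)
```

# The problem

A multi-terabyte genomic analysis — here the motivating case is ensemble
DNase-seq footprinting across 27 human tissue types, ending in candidate
transcription-factor binding sites (TFBSs) — produces families of datasets
that must be enumerable (so additions and deletions are detectable),
verifiable (fixity via checksums), described (metadata and provenance
travel with the data), distributable (elements may live in several remote
locations) and identifiable (a concise, persistent name per dataset
instance). `fairbag` implements that data lifecycle as composable pieces:
checksum-manifested bags with remote references, checksum-bound
identifiers with landing records, recursive materialization, manifest
conversion and bookkeeping, a FAIRness rubric, and the final
interval-intersection stage.

# Bags

A bag is a BagIt 1.0 directory: a declaration (`bagit.txt`, fixed at
version 1.0 / UTF-8), payload under `data/`, one payload manifest per
checksum algorithm, `bag-info.txt` label/value pairs, and tag manifests
covering every non-payload file. Two extensions matter:

* **Remote references.** `fetch.txt` lists `(locator, length, path)`
  triples, one per line; the locator may be a URL or an identifier CURIE.
  A referenced path has a payload-manifest entry (so its digest is fixed
  before its bytes arrive) but no local bytes: the bag is *holey*. Lengths
  may be unknown (`-`). `%`, CR and LF in target paths are percent-encoded;
  the length must be a decimal integer, read back strictly.
* **Research Object manifest.** `metadata/manifest.json` is a minimal
  JSON-LD document — context, `createdOn`/`createdBy`, aggregates (every
  payload entry and remote reference), annotations — deliberately not a
  full RO-Crate/ORE vocabulary. Because it is a tag file, metadata
  tampering is caught by the same fixity machinery as payload tampering.

Checksums default to md5 **and** sha256: upstream repositories commonly
publish md5, while the identifier registry binds sha256; recording both
lets either side verify without recomputation. Any recorded digest is
verified during full validation.

`Payload-Oxum` counts octets and streams over local *and* remote entries,
because it should describe the dataset a holey bag represents rather than
the bytes currently on disk. The consequence is accepted explicitly: if
any remote length is unknown, fast validation reports the Oxum
unverifiable instead of guessing.

Determinism choices: manifests sort byte-lexicographically (C locale,
radix sort), all tag files are LF-terminated UTF-8, and archives (`zip`,
`tgz`) contain exactly one top-level directory named after the bag. This
makes serialization byte-stable given fixed timestamps, which the test
suite exploits (`baggingDate`, `createdOn`, and registry `created` are all
injectable).

Validation never signals conditions for findings: `structural` checks the
layout and enumeration, `fast` adds the Oxum, `full` recomputes every
recorded digest. A holey bag is *structurally valid but incomplete*;
`valid` means structurally sound, complete, no fixity errors, no
unenumerated files.

# Identifiers

Minted identifiers are CURIEs `prefix:suffix` (default prefix `minid`,
suffix six lowercase base-36 characters, collision-checked with bounded
retries). A record stores title, creator, creation time, the sha256 of the
identified content, an ordered location list, a status, and open metadata.
The registry is an append-only JSON-lines file — every update appends a
new document and the latest wins — so it survives restarts, keeps history,
and needs no service. Three semantics are load-bearing:

* the checksum is immutable after minting (identifiers name *instances*);
* locations only grow, idempotently, in registration order — choosing
  among copies is the consumer's business, so no bandwidth heuristics;
* tombstoned records still resolve: the landing record outlives the data.

With a seed supplied, suffix *i* of the stream is a pure function of
(seed, number of existing records), giving reproducible fixtures without
touching the caller's RNG. Without a seed, suffixes are random.

# Materialization

Planning resolves each non-present entry to candidate URLs (a CURIE's
registry locations in order; a plain URL as itself); an unresolvable CURIE
becomes a non-fatal `unavailable` outcome, since a collection may
legitimately reference data its reader cannot yet access. Fetching tries
candidates in order with `file://` and `http(s)://` transports (three
attempts with exponential backoff for HTTP; anything else is
unavailable), verifies length and every expected digest on a temporary
file, and only then moves it into place — no partially verified bytes
ever occupy a payload path. Failed copies are quarantined beside the bag,
named by their observed digest, for post-mortem.

Recursive materialization expands payload entries that are themselves
serialized bags — detected by the registry record's
`content_type` (`bag+zip`/`bag+tgz`) with a structural sniff for
`bagit.txt` as fallback — into a scratch area (so the outer bag's own
enumeration stays intact), down to a depth limit. At the limit, inner
archives are fetched but left unexpanded and reported as such. Each inner
bag is validated independently; one corrupt child does not affect its
siblings.

# Manifest conversion and bookkeeping

The converter takes a tab-separated metadata export (ENCODE-portal column
headers by default, remappable via `encodeColumnMap()`). Parsing is
strict — a size of `12,345` is an error, not `12345` — because these
numbers feed byte-level length checks and provenance totals. A *replicate*
is a (biosample, replicate) pair; one replicate may span several files, so
file counts and replicate counts are tracked separately. Target paths are
`data/<file accession>.<lowercased format>`. The grouping key is the
organ/tissue term as given: the catalog's grouping into 27 organ terms is
treated as input, not recomputed by ontology mapping.

Each produced bag embeds the source rows and the query record verbatim as
annotations — the same portal query run at a different time may return
different rows, so the recorded result, not the query text, is the
reproducible object. Partitioning produces one minted bag per tissue and a
minted bag of bags referencing the per-tissue identifiers by CURIE.

`planProducts()` is pure combinatorics: per tissue one input bag; per
{tissue, seed length} one alignment bag; per {biosample, seed} one merged
BAM; per {tissue, seed, method} one footprint file and one TFBS file. For
the 27-tissue preset with seeds {16, 20} and methods {HINT, Wellington}
this yields 54 alignment bags, 386 merged files, and 108 footprint and
TFBS files. Where the study's own tables describe the footprint dataset
both as two BED files per biosample and as one file per
{tissue, seed, method}, the planner follows the per-{tissue, seed, method}
accounting (108), which matches the downstream intersection stage's file
count.

# The FAIR rubric

Sixteen ordered criteria, each a single predicate over one descriptor
field. The underlying questionnaire of hosted assessment services is not
reproduced; in particular "Protocol to access restricted content" is a
declared property, not probed. `assess()` refuses descriptors with
unstated flags. `assessBag()` instead derives what the artifacts can
demonstrate — identifier criteria from the registry record, metadata
criteria from the embedded RO manifest, access criteria from the recorded
locations — and treats everything neither derivable nor declared as
unmet: an unevidenced property is not a satisfied one. The 13 case-study
profiles (`caseStudyDescriptors()`) encode six datasets and seven tools,
all identified, documented and licensed, web-discoverable only for the
initial repository dataset and the tools, and certified for none; the
published verdict matrix marks all tools web-discoverable even though
only the initial dataset is indexed by web search — the profiles follow
the matrix, and the tension is noted here rather than resolved.

# Interval intersection

Footprints and motif hits are plain data frames in BED convention:
0-based, half-open, `start < end`, nonempty sequence name; hit p-values
in [0, 1]. Overlap is computed with GenomicRanges (converting to 1-based
closed coordinates at the boundary), one candidate per (footprint, hit)
pair sharing at least one base on the same sequence. Two deliberate
choices: *any* overlap suffices (full containment of the hit is not
required — the choice is flagged because either reading is defensible),
and strand never gates the overlap (no strand rule is imposed by the
method; the hit's strand is carried into the output). Output is BED6+
with the motif id in the name column, sorted by (chrom, start, motif_id)
with further deterministic tie-breaks so files are byte-stable. The
correctness contract is equality with a quadratic all-pairs oracle, which
the test suite enforces on seeded random instances up to 500×500.

# What the synthetic generators emulate — and what they do not

`generateFixtureManifest()` reproduces the *structure* of a portal
export: per-tissue biosample and replicate counts (the bundled
`table1Tissues()` preset carries the study's 27 tissues, 193 biosamples
and 1,355 replicates exactly), accession-like identifiers, real payload
files whose md5 and size columns are computed from the bytes actually
written, and `file://` URLs into a local store. Files are deliberately
small (1–4 kB by default): the machinery under test — enumeration,
fixity, resolution, fallback — is size-independent, and the manifest's
size column always matches the generated file so length checks stay
meaningful. One file per replicate is generated; the real corpus splits
some replicates across several FASTQ files, so real *file* totals exceed
replicate totals, which is why file counts are never asserted against the
study's printed file count. The generators also do not emulate sequencing
content, portal API behavior, access control, or network failure modes
beyond what the tamper utility (`tamperFile()`, a one-byte XOR
involution) and multi-location fallback fixtures exercise — passing tests
demonstrate the packaging and verification machinery, not performance at
terabyte scale.

All generation is reproducible from (spec, seed) via an isolated RNG
scope, and no fixture depends on the network or the wall clock.

# Problem sizes and runtime

The suite runs at sizes chosen to exercise every contract in seconds:
random bags of 3–7 small files across all three layouts; materialization
trees of 3 inner bags; the full 27-tissue preset (1,355 generated files,
a few MB) for partitioning and bookkeeping; intersection instances up to
500×500 against the quadratic oracle. The full suite completes in well
under a minute on a single CPU.

# Known limitations

* Transports are `file://` and plain `http(s)://`; no authenticated
  transfer fabrics, no parallel streams, no resumable downloads.
* The identifier registry is local; no integration with global resolvers
  (n2t.net, identifiers.org) or DOI/ARK backends, though the CURIE form
  and landing-record content mirror that ecosystem.
* The RO manifest is a fixed minimal profile; no ontology validation and
  no nested provenance chains.
* Holey-bag support is `fetch.txt` only; no encryption, no streaming
  archive readers.
* The footprinting and motif-scanning algorithms themselves (alignment,
  peak calling, HINT/Wellington, PWM scanning) are out of scope: their
  inputs and outputs are what gets packaged, planned and intersected
  here.
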