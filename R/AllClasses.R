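#' @import methods
NULL

emptyPayloadDF <- function(algorithms = character()) {
  df <- data.frame(path = character(), size_bytes = numeric(),
                   present = logical(), stringsAsFactors = FALSE)
  for (a in algorithms) df[[a]] <- character()
  df
}

emptyFetchDF <- function() {
  data.frame(locator = character(), length_bytes = numeric(),
             path = character(), stringsAsFactors = FALSE)
}

#' BDBag: a BagIt bag with remote references and embedded metadata
#'
#' In-memory representation of an on-disk BDBag. The payload slot enumerates
#' every payload stream -- locally present files under \code{data/} as well as
#' remote references listed in \code{fetch.txt} -- with one column per
#' recorded checksum algorithm. A bag with at least one non-present payload
#' entry is \emph{holey}; a bag whose entries are all present is
#' \emph{complete}.
#'
#' @slot root bag directory on disk.
#' @slot version BagIt declaration version (fixed at "1.0").
#' @slot encoding tag file character encoding (fixed at "UTF-8").
#' @slot algorithms checksum algorithms recorded in the payload manifests.
#' @slot payload data.frame with columns \code{path}, \code{size_bytes},
#'   \code{present} and one lowercase hex digest column per algorithm
#'   (\code{NA} where a digest is not recorded).
#' @slot fetch data.frame of remote references with columns \code{locator}
#'   (URL or identifier CURIE), \code{length_bytes} (\code{NA} = unknown) and
#'   \code{path} (target under \code{data/}).
#' @slot bagInfo named character vector of ordered \code{bag-info.txt} pairs.
#' @slot tagFiles data.frame of non-payload files covered by the tag
#'   manifests (column \code{path} plus digest columns).
#' @slot roManifest a \linkS4class{RoManifest}, or \code{NULL}.
#' @exportClass BDBag
setClass("BDBag", representation(
  root = "character",
  version = "character",
  encoding = "character",
  algorithms = "character",
  payload = "data.frame",
  fetch = "data.frame",
  bagInfo = "character",
  tagFiles = "data.frame",
  roManifest = "ANY"
))

setValidity("BDBag", function(object) {
  msgs <- character()
  p <- object@payload
  if (nrow(p)) {
    if (any(!startsWith(p$path, "data/")))
      msgs <- c(msgs, "payload paths must start with 'data/'")
    if (any(vapply(strsplit(p$path, "/", fixed = TRUE),
                   function(x) any(x %in% c("..", "")), logical(1))))
      msgs <- c(msgs, "payload paths must not contain '..' or empty segments")
    if (anyDuplicated(p$path))
      msgs <- c(msgs, "duplicated payload paths")
    digested <- rowSums(!is.na(as.matrix(p[, object@algorithms, drop = FALSE])))
    if (any(digested == 0))
      msgs <- c(msgs, "every payload entry must carry at least one digest")
  }
  f <- object@fetch
  if (nrow(f) && !all(f$path %in% p$path))
    msgs <- c(msgs, "every fetch entry must have a payload entry")
  if (length(msgs)) msgs else TRUE
})

#' Result of validating a bag
#'
#' @slot structuralOK layout and manifests are well formed.
#' @slot complete every payload entry is locally present.
#' @slot fixityErrors data.frame (path, algorithm, expected, observed).
#' @slot missingEntries payload paths with no local bytes.
#' @slot extraFiles files under data/ not listed in any payload manifest.
#' @slot oxumOK Payload-Oxum agrees with the enumerated payload (NA when it
#'   cannot be checked, e.g. unknown remote lengths).
#' @slot oxumReason explanation when oxumOK is not TRUE.
#' @slot mode validation mode that produced the report.
#' @exportClass BagValidation
setClass("BagValidation", representation(
  structuralOK = "logical",
  complete = "logical",
  fixityErrors = "data.frame",
  missingEntries = "character",
  extraFiles = "character",
  oxumOK = "logical",
  oxumReason = "character",
  mode = "character"
))

#' Research Object manifest embedded in a bag
#'
#' Minimal JSON-LD profile: a context list, creation attribution, the
#' aggregated resources (every payload entry and remote reference of the
#' enclosing bag), and annotations about those resources or the bag itself.
#'
#' @slot context character vector of JSON-LD context URIs.
#' @slot createdOn RFC 3339 UTC timestamp.
#' @slot createdBy list with \code{name} and optional \code{uri}.
#' @slot aggregates data.frame with columns \code{uri} (bag-relative path or
#'   remote locator), \code{mediatype}, \code{bundledAs} (target path for
#'   remote aggregates, else NA).
#' @slot annotations data.frame with columns \code{about} and \code{content}.
#' @exportClass RoManifest
setClass("RoManifest", representation(
  context = "character",
  createdOn = "character",
  createdBy = "list",
  aggregates = "data.frame",
  annotations = "data.frame"
))

#' A checksum-bound persistent-identifier landing record
#'
#' @slot curie compact identifier "prefix:suffix".
#' @slot title human title of the identified content.
#' @slot creator agent name.
#' @slot created RFC 3339 UTC timestamp.
#' @slot checksumAlgorithm algorithm of the content checksum (sha256).
#' @slot checksum lowercase hex digest of the identified content.
#' @slot locations ordered URLs where copies may be obtained.
#' @slot status "active" or "tombstoned" (the landing record outlives the
#'   data it names).
#' @slot extra open named list of additional metadata.
#' @exportClass IdentifierRecord
setClass("IdentifierRecord", representation(
  curie = "character",
  title = "character",
  creator = "character",
  created = "character",
  checksumAlgorithm = "character",
  checksum = "character",
  locations = "character",
  status = "character",
  extra = "list"
))

setValidity("IdentifierRecord", function(object) {
  msgs <- character()
  if (!isCurie(object@curie)) msgs <- c(msgs, "curie must be 'prefix:suffix'")
  if (!object@status %in% c("active", "tombstoned"))
    msgs <- c(msgs, "status must be 'active' or 'tombstoned'")
  if (length(msgs)) msgs else TRUE
})

#' A local append-only identifier registry
#'
#' Records are stored as one JSON document per line; updates append a new
#' line for the same CURIE and the latest line wins. This keeps the store
#' human-inspectable and makes every historical state recoverable.
#'
#' @slot path path of the JSON-lines record store.
#' @slot prefix CURIE prefix for minted identifiers.
#' @slot suffixLength length of minted suffixes.
#' @exportClass MinidRegistry
setClass("MinidRegistry", representation(
  path = "character",
  prefix = "character",
  suffixLength = "integer"
))

#' Plan for resolving and fetching a holey bag's remote references
#'
#' @slot entries list of per-entry plans: \code{path}, \code{locator},
#'   \code{candidates} (URLs in preference order), \code{digests} (named),
#'   \code{length_bytes}, \code{status} ("planned" or "unavailable").
#' @slot bagRoot root of the bag the plan was built for.
#' @exportClass FetchPlan
setClass("FetchPlan", representation(
  entries = "list",
  bagRoot = "character"
))

#' Outcome of executing a FetchPlan
#'
#' @slot outcomes data.frame (path, status, url, reason); status is one of
#'   fetched-verified, fetched-corrupt, unavailable, skipped.
#' @slot bytesFetched total verified bytes placed into the payload.
#' @slot report post-fetch \linkS4class{BagValidation} (full mode).
#' @exportClass FetchResult
setClass("FetchResult", representation(
  outcomes = "data.frame",
  bytesFetched = "numeric",
  report = "ANY"
))

#' FAIR-relevant properties of a dataset or tool
#'
#' One logical flag per rubric criterion (besides the identifier itself).
#' \code{NA} means "not stated"; \code{\link{assess}} refuses to score a
#' descriptor with NA flags, while \code{\link{assessBag}} derives what it
#' can from a bag and registry record.
#'
#' @slot kind "dataset" or "software".
#' @slot identifier identifier CURIE or URL (NA when the resource has none).
#' @slot flags named logical vector, one element per declarable criterion.
#' @exportClass ResourceDescriptor
setClass("ResourceDescriptor", representation(
  kind = "character",
  identifier = "character",
  flags = "logical"
))

#' Verdicts of the 16-criterion FAIR rubric
#'
#' @slot resource label of the assessed resource.
#' @slot verdicts named logical vector of length 16, ordered as the rubric.
#' @slot satisfiedCount number of criteria met.
#' @exportClass RubricResult
setClass("RubricResult", representation(
  resource = "character",
  verdicts = "logical",
  satisfiedCount = "integer"
))

setValidity("RubricResult", function(object) {
  if (length(object@verdicts) != 16L) return("exactly 16 verdicts required")
  if (object@satisfiedCount != sum(object@verdicts))
    return("satisfiedCount must equal the number of TRUE verdicts")
  TRUE
})

#' Fan-out plan for the footprinting pipeline
#'
#' Enumerates the products of each pipeline stage for a set of tissue
#' groups, alignment seed lengths, and footprinting methods, together with a
#' provenance ledger mapping every product to its input group.
#'
#' @slot tissues tissue group labels.
#' @slot seeds alignment seed lengths.
#' @slot methods footprinting method labels.
#' @slot nBiosamples named integer, biosamples per tissue.
#' @slot counts named numeric of product counts per stage.
#' @slot products data.frame ledger: stage, product, tissue, seed, method,
#'   input.
#' @exportClass PipelinePlan
setClass("PipelinePlan", representation(
  tissues = "character",
  seeds = "numeric",
  methods = "character",
  nBiosamples = "integer",
  counts = "numeric",
  products = "data.frame"
))
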