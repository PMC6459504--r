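#' Open (or create) a local identifier registry
#'
#' The registry is an append-only JSON-lines store: every mint, location
#' addition, or tombstoning appends one record document, and resolution
#' returns the latest document for a CURIE. The store survives process
#' restarts and is trivially inspectable.
#'
#' @param path path of the record store file (created if absent).
#' @param prefix CURIE prefix for minted identifiers.
#' @param suffixLength length of minted suffixes (lowercase base-36).
#' @return a \linkS4class{MinidRegistry}.
#' @export
openRegistry <- function(path, prefix = "minid", suffixLength = 6L) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!file.exists(path)) file.create(path)
  new("MinidRegistry", path = normalizePath(path), prefix = prefix,
      suffixLength = as.integer(suffixLength))
}

readRegistryLines <- function(registry) {
  lines <- readLinesUTF8(registry@path)
  lapply(lines[nzchar(lines)], jsonlite::fromJSON, simplifyVector = TRUE)
}

recordToList <- function(record) {
  list(curie = record@curie, title = record@title, creator = record@creator,
       created = record@created,
       checksum_algorithm = record@checksumAlgorithm,
       checksum = record@checksum,
       locations = as.list(record@locations), status = record@status,
       extra = record@extra)
}

recordFromList <- function(x) {
  new("IdentifierRecord", curie = x$curie, title = x$title,
      creator = x$creator, created = x$created,
      checksumAlgorithm = x$checksum_algorithm, checksum = x$checksum,
      locations = as.character(unlist(x$locations)),
      status = x$status,
      extra = if (is.null(x$extra) || length(x$extra) == 0) list()
              else as.list(x$extra))
}

appendRecord <- function(registry, record) {
  line <- jsonlite::toJSON(recordToList(record), auto_unbox = TRUE,
                           null = "null")
  con <- file(registry@path, open = "ab")
  on.exit(close(con))
  writeLines(line, con, sep = "\n", useBytes = TRUE)
  invisible(record)
}

SUFFIX_ALPHABET <- c(letters, 0:9)

## Deterministic suffix stream: position i of the stream for a given seed is
## a function of (seed, i) only, so test fixtures are stable. Without a
## seed, suffixes are drawn from R's RNG without disturbing the caller's
## random state.
suffixAt <- function(seed, i, n) {
  h <- rawDigest(sprintf("%d:%d", seed, i), "sha256")
  vals <- strtoi(substring(h, seq(1, 2 * n, 2), seq(2, 2 * n, 2)), 16L)
  paste(SUFFIX_ALPHABET[vals %% 36L + 1L], collapse = "")
}

randomSuffix <- function(n) {
  withr::with_preserve_seed({
    set.seed(NULL)
    paste(sample(SUFFIX_ALPHABET, n, replace = TRUE), collapse = "")
  })
}

#' Mint a checksum-bound identifier
#'
#' Creates a new unique CURIE bound to the sha256 digest of the identified
#' content, persists its landing record, and returns it. Two mints of
#' identical content yield distinct identifiers with equal checksums:
#' identifiers name dataset instances, not content.
#'
#' @param registry a \linkS4class{MinidRegistry}.
#' @param file content to identify (digested with sha256); alternatively
#'   supply \code{checksum} directly.
#' @param title,creator landing-record metadata.
#' @param locations ordered URLs where copies of the content live.
#' @param checksum precomputed lowercase sha256 hex digest.
#' @param seed optional integer making the minted suffix sequence
#'   deterministic (suffix i of a seed's stream is a pure function of the
#'   seed and the number of records already in the registry).
#' @param extra named list of open metadata (e.g.
#'   \code{content_type = "bag+zip"} marking a serialized bag).
#' @param created optional RFC 3339 timestamp override.
#' @return the minted \linkS4class{IdentifierRecord}.
#' @export
mintMinid <- function(registry, file = NULL, title = "", creator = "",
                      locations = character(), checksum = NULL, seed = NULL,
                      extra = list(), created = NULL) {
  stopifnot(is(registry, "MinidRegistry"))
  if (is.null(checksum)) {
    if (is.null(file)) {
      stop(fairbagError("input", "either a content file or a checksum is required"))
    }
    if (!file.exists(file)) {
      stop(fairbagError("io", sprintf("cannot read content file '%s'", file)))
    }
    checksum <- fileDigest(file, "sha256")
  }
  existing <- vapply(readRegistryLines(registry), `[[`, "", "curie")
  n <- registry@suffixLength
  counter <- length(existing)
  curie <- NULL
  for (try in seq_len(100L)) {
    suffix <- if (is.null(seed)) randomSuffix(n)
              else suffixAt(seed, counter + try - 1L, n)
    cand <- paste0(registry@prefix, ":", suffix)
    if (!cand %in% existing) { curie <- cand; break }
  }
  if (is.null(curie)) {
    stop(fairbagError("registry", "suffix collision persisted after bounded retries"))
  }
  record <- new("IdentifierRecord", curie = curie, title = title,
                creator = creator,
                created = if (is.null(created)) rfc3339Now() else created,
                checksumAlgorithm = "sha256", checksum = tolower(checksum),
                locations = unique(locations), status = "active",
                extra = extra)
  appendRecord(registry, record)
  record
}

#' Resolve an identifier to its landing record
#'
#' Resolution succeeds for tombstoned identifiers too: the landing record
#' outlives the data it names.
#'
#' @param registry a \linkS4class{MinidRegistry}.
#' @param curie identifier text "prefix:suffix".
#' @return the latest \linkS4class{IdentifierRecord} for the CURIE.
#' @export
resolveMinid <- function(registry, curie) {
  parseCurie(curie)
  recs <- readRegistryLines(registry)
  hits <- which(vapply(recs, `[[`, "", "curie") == curie)
  if (length(hits) == 0L) {
    stop(fairbagError("not_found", sprintf("unknown identifier '%s'", curie)))
  }
  recordFromList(recs[[max(hits)]])
}

#' Register an additional storage location
#'
#' Locations may only grow (idempotently) and keep their registration
#' order; which copy to use is the consumer's choice.
#'
#' @param registry a \linkS4class{MinidRegistry}.
#' @param curie identifier to update.
#' @param url location to append.
#' @return the updated \linkS4class{IdentifierRecord}.
#' @export
addLocation <- function(registry, curie, url) {
  record <- resolveMinid(registry, curie)
  if (record@status == "tombstoned") {
    stop(fairbagError("immutable",
                      sprintf("'%s' is tombstoned; locations are frozen", curie)))
  }
  if (!url %in% record@locations) {
    record@locations <- c(record@locations, url)
    appendRecord(registry, record)
  }
  record
}

#' Tombstone an identifier
#'
#' Marks the record as naming content that is no longer maintained; the
#' record itself, including its checksum and locations, remains resolvable.
#'
#' @param registry a \linkS4class{MinidRegistry}.
#' @param curie identifier to tombstone.
#' @return the tombstoned \linkS4class{IdentifierRecord}.
#' @export
tombstoneMinid <- function(registry, curie) {
  record <- resolveMinid(registry, curie)
  record@status <- "tombstoned"
  appendRecord(registry, record)
  record
}

#' Render a landing record
#'
#' The machine form is a JSON document containing every field of the record
#' (parseable back into an equal record with \code{parseRecordJSON}); the
#' human form is an HTML landing page listing title, creator, creation
#' date, the content checksum, and a link for each registered location.
#'
#' @param record an \linkS4class{IdentifierRecord}.
#' @param format "machine" (JSON) or "human" (HTML).
#' @return a single string.
#' @export
renderRecord <- function(record, format = c("machine", "human")) {
  format <- match.arg(format)
  if (format == "machine") {
    return(as.character(jsonlite::toJSON(recordToList(record),
                                         auto_unbox = TRUE, pretty = TRUE)))
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  links <- sprintf('    <li><a href="%s">%s</a></li>',
                   esc(record@locations), esc(record@locations))
  paste(c("<!DOCTYPE html>",
          "<html><head><title>", esc(record@curie), "</title></head><body>",
          sprintf("<h1>%s</h1>", esc(record@title)),
          sprintf("<p>Identifier: <code>%s</code> (%s)</p>",
                  esc(record@curie), esc(record@status)),
          sprintf("<p>Creator: %s</p>", esc(record@creator)),
          sprintf("<p>Created: %s</p>", esc(record@created)),
          sprintf("<p>Checksum (%s): <code>%s</code></p>",
                  esc(record@checksumAlgorithm), esc(record@checksum)),
          sprintf("<h2>Locations (%d)</h2>", length(record@locations)),
          "  <ul>", links, "  </ul>",
          "</body></html>"),
        collapse = "\n")
}

#' Parse a machine-rendered landing record
#'
#' @param json JSON text produced by \code{renderRecord(..., "machine")}.
#' @return an \linkS4class{IdentifierRecord}.
#' @export
parseRecordJSON <- function(json) {
  recordFromList(jsonlite::fromJSON(json, simplifyVector = TRUE))
}

#' Verify local content against an identifier's checksum
#'
#' @param registry a \linkS4class{MinidRegistry}.
#' @param curie identifier whose checksum to verify against.
#' @param file local copy of the content.
#' @return \code{TRUE} iff the recomputed digest equals the record's
#'   checksum. Works for tombstoned records too; checksums outlive data.
#' @export
verifyContent <- function(registry, curie, file) {
  record <- resolveMinid(registry, curie)
  if (!file.exists(file)) {
    stop(fairbagError("io", sprintf("cannot read '%s'", file)))
  }
  identical(fileDigest(file, record@checksumAlgorithm), record@checksum)
}
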