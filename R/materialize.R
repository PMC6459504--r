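#' Plan the fetches needed to materialize a holey bag
#'
#' Each non-present payload entry contributes exactly one plan entry.
#' Identifier CURIEs are resolved through the registry to the record's
#' ordered storage locations (candidate URLs are tried in that order);
#' plain URLs pass through as a single candidate. An unresolvable CURIE is
#' recorded as \code{unavailable} rather than raising an error.
#'
#' @param bag a \linkS4class{BDBag}.
#' @param registry optional \linkS4class{MinidRegistry} for CURIE locators.
#' @param selector optional glob restricting target paths (e.g.
#'   \code{"data/*.fastq"}), supporting fetching a subset of the remote
#'   files.
#' @return a \linkS4class{FetchPlan}.
#' @export
planFetch <- function(bag, registry = NULL, selector = NULL) {
  stopifnot(is(bag, "BDBag"))
  todo <- bag@fetch[!file.exists(file.path(bag@root, bag@fetch$path)), ,
                    drop = FALSE]
  if (!is.null(selector)) {
    todo <- todo[grepl(utils::glob2rx(selector), todo$path), , drop = FALSE]
  }
  digestCols <- intersect(bag@algorithms, names(bag@payload))
  entries <- lapply(seq_len(nrow(todo)), function(i) {
    locator <- todo$locator[i]
    path <- todo$path[i]
    row <- bag@payload[bag@payload$path == path, , drop = FALSE]
    digests <- unlist(row[1, digestCols, drop = FALSE])
    digests <- digests[!is.na(digests)]
    if (isCurie(locator)) {
      record <- tryCatch(resolveMinid(registry, locator), error = function(e) NULL)
      candidates <- if (is.null(record)) character() else record@locations
      if (!is.null(record) && !"sha256" %in% names(digests)) {
        digests <- c(digests, sha256 = record@checksum)
      }
    } else {
      candidates <- locator
    }
    list(path = path, locator = locator, candidates = candidates,
         digests = digests, length_bytes = todo$length_bytes[i],
         status = if (length(candidates)) "planned" else "unavailable")
  })
  new("FetchPlan", entries = entries, bagRoot = bag@root)
}

## Retrieve one URL to `dest`; file:// by copy, http(s):// with bounded
## retries and backoff. Returns TRUE on apparent success.
retrieveUrl <- function(url, dest, attempts = 3L) {
  if (startsWith(url, "file://")) {
    src <- pathFromFileUrl(url)
    return(file.exists(src) && file.copy(src, dest, overwrite = TRUE))
  }
  if (grepl("^https?://", url)) {
    for (i in seq_len(attempts)) {
      ok <- tryCatch(
        utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
        error = function(e) FALSE, warning = function(w) FALSE)
      if (ok) return(TRUE)
      Sys.sleep(0.2 * 2^(i - 1))
    }
    return(FALSE)
  }
  FALSE  # unsupported transport
}

verifyDownload <- function(tmp, digests, lengthBytes) {
  if (!is.na(lengthBytes) && file.size(tmp) != lengthBytes) return(FALSE)
  for (a in names(digests)) {
    if (!identical(fileDigest(tmp, a), tolower(digests[[a]]))) return(FALSE)
  }
  TRUE
}

#' Execute a fetch plan
#'
#' For every entry the candidate URLs are tried in order; a download only
#' reaches its target path after its length and every expected digest have
#' verified (verify-then-place, so no partially verified file ever occupies
#' a payload path). Downloads that fail verification on every candidate are
#' quarantined beside the bag for post-mortem, named by their observed
#' digest. The bag is revalidated (full mode) afterwards.
#'
#' @param bag the \linkS4class{BDBag} being materialized.
#' @param plan a \linkS4class{FetchPlan} from \code{\link{planFetch}}.
#' @return a \linkS4class{FetchResult}.
#' @export
fetchAll <- function(bag, plan) {
  stopifnot(is(bag, "BDBag"), is(plan, "FetchPlan"))
  root <- bag@root
  quarantine <- paste0(root, ".quarantine")
  outcomes <- data.frame(path = character(), status = character(),
                         url = character(), reason = character(),
                         stringsAsFactors = FALSE)
  bytes <- 0
  for (entry in plan@entries) {
    status <- "unavailable"; urlUsed <- NA_character_; reason <- ""
    if (entry$status == "unavailable") {
      reason <- sprintf("locator '%s' did not resolve", entry$locator)
    } else {
      sawCorrupt <- FALSE
      for (url in entry$candidates) {
        tmp <- tempfile("fetch-")
        if (!retrieveUrl(url, tmp)) { unlink(tmp); next }
        if (verifyDownload(tmp, entry$digests, entry$length_bytes)) {
          dest <- file.path(root, entry$path)
          dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
          if (!file.rename(tmp, dest)) { file.copy(tmp, dest); unlink(tmp) }
          bytes <- bytes + file.size(dest)
          status <- "fetched-verified"; urlUsed <- url
          break
        }
        sawCorrupt <- TRUE
        dir.create(quarantine, showWarnings = FALSE)
        file.rename(tmp, file.path(quarantine, fileDigest(tmp, "sha256")))
      }
      if (status != "fetched-verified") {
        if (sawCorrupt) {
          status <- "fetched-corrupt"
          reason <- "digest or length mismatch on every retrievable candidate"
        } else {
          reason <- "no candidate could be retrieved"
        }
      }
    }
    outcomes <- rbind(outcomes,
                      data.frame(path = entry$path, status = status,
                                 url = urlUsed, reason = reason,
                                 stringsAsFactors = FALSE))
  }
  report <- validateBag(readBag(root), mode = "full")
  new("FetchResult", outcomes = outcomes, bytesFetched = as.numeric(bytes),
      report = report)
}

#' Materialize a holey bag
#'
#' Convenience wrapper: plan, fetch, and return the result.
#'
#' @inheritParams planFetch
#' @return a \linkS4class{FetchResult}.
#' @export
materializeBag <- function(bag, registry = NULL, selector = NULL) {
  fetchAll(bag, planFetch(bag, registry, selector))
}

## Is this payload file a serialized bag? Prefer the registry record's
## content-type; fall back to a structural sniff for bagit.txt at the
## archive root.
isSerializedBag <- function(path, record = NULL) {
  if (!is.null(record)) {
    ct <- record@extra[["content_type"]]
    if (!is.null(ct)) return(ct %in% c("bag+zip", "bag+tgz"))
  }
  if (grepl("\\.zip$", path)) {
    lst <- tryCatch(utils::unzip(path, list = TRUE)$Name, error = function(e) character())
    return(any(grepl("^[^/]+/bagit.txt$", lst)))
  }
  if (grepl("\\.(tgz|tar\\.gz)$", path)) {
    lst <- tryCatch(utils::untar(path, list = TRUE), error = function(e) character())
    return(any(grepl("^[^/]+/bagit.txt$", lst)))
  }
  FALSE
}

#' Recursively materialize a bag of bags
#'
#' After fetching the bag's own remote references, every payload entry that
#' is itself a serialized bag (by registry content-type, or a structural
#' sniff for a \code{bagit.txt} at the archive root) is unpacked to a
#' scratch area and materialized in turn, up to \code{maxDepth} levels.
#' Inner bags are expanded outside the outer bag's payload so the outer
#' bag's own enumeration stays intact.
#'
#' @param bag a \linkS4class{BDBag} (typically holey, referencing inner
#'   bags by identifier).
#' @param registry a \linkS4class{MinidRegistry}.
#' @param maxDepth recursion limit (>= 1); depth 1 fetches the inner
#'   archives without expanding them.
#' @param workDir scratch directory for expanded inner bags.
#' @return a nested report: \code{root}, \code{valid}, \code{complete},
#'   \code{fetch} (the \linkS4class{FetchResult}), \code{children} (one
#'   report per expanded inner bag), \code{unexpanded} (archives left
#'   unexpanded at the depth limit).
#' @export
materializeRecursive <- function(bag, registry, maxDepth = 5L,
                                 workDir = tempfile("materialize-")) {
  stopifnot(maxDepth >= 1L)
  dir.create(workDir, recursive = TRUE, showWarnings = FALSE)

  result <- materializeBag(bag, registry)
  bag <- readBag(bag@root)

  children <- list()
  unexpanded <- character()
  arch <- bag@payload$path[bag@payload$present]
  for (i in seq_along(arch)) {
    p <- arch[i]
    full <- file.path(bag@root, p)
    loc <- bag@fetch$locator[match(p, bag@fetch$path)]
    record <- if (!is.na(loc) && isCurie(loc)) {
      tryCatch(resolveMinid(registry, loc), error = function(e) NULL)
    }
    if (!isSerializedBag(full, record)) next
    if (maxDepth <= 1L) {
      unexpanded <- c(unexpanded, p)
      next
    }
    innerRoot <- tryCatch(
      unpackArchive(full, file.path(workDir, sprintf("inner-%03d", i))),
      error = function(e) NULL)
    if (is.null(innerRoot)) {
      unexpanded <- c(unexpanded, p)
      next
    }
    inner <- tryCatch(readBag(innerRoot), error = function(e) NULL)
    if (is.null(inner)) {
      children[[p]] <- list(root = innerRoot, valid = FALSE, complete = FALSE,
                            fetch = NULL, children = list(),
                            unexpanded = character())
      next
    }
    children[[p]] <- materializeRecursive(inner, registry,
                                          maxDepth = maxDepth - 1L,
                                          workDir = file.path(workDir,
                                                              sprintf("sub-%03d", i)))
  }

  list(root = bag@root,
       valid = isValid(result@report),
       complete = isComplete(result@report),
       fetch = result,
       children = children,
       unexpanded = unexpanded)
}
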