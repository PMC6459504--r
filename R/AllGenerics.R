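#' @include AllClasses.R
NULL

#' Accessors for bag and report objects
#'
#' @param x a \linkS4class{BDBag}, \linkS4class{BagValidation},
#'   \linkS4class{FetchResult}, \linkS4class{RubricResult} or
#'   \linkS4class{PipelinePlan}.
#' @return the requested component.
#' @name accessors
#' @aliases bagRoot payload remoteRefs bagInfo isHoley isComplete isValid
#'   fixityErrors missingEntries extraFiles satisfiedCount verdicts
#'   productCounts productLedger
NULL

#' @rdname accessors
#' @export
setGeneric("bagRoot", function(x) standardGeneric("bagRoot"))
#' @rdname accessors
#' @export
setGeneric("payload", function(x) standardGeneric("payload"))
#' @rdname accessors
#' @export
setGeneric("remoteRefs", function(x) standardGeneric("remoteRefs"))
#' @rdname accessors
#' @export
setGeneric("bagInfo", function(x) standardGeneric("bagInfo"))
#' @rdname accessors
#' @export
setGeneric("isHoley", function(x) standardGeneric("isHoley"))
#' @rdname accessors
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))
#' @rdname accessors
#' @export
setGeneric("isValid", function(x) standardGeneric("isValid"))
#' @rdname accessors
#' @export
setGeneric("fixityErrors", function(x) standardGeneric("fixityErrors"))
#' @rdname accessors
#' @export
setGeneric("missingEntries", function(x) standardGeneric("missingEntries"))
#' @rdname accessors
#' @export
setGeneric("extraFiles", function(x) standardGeneric("extraFiles"))
#' @rdname accessors
#' @export
setGeneric("satisfiedCount", function(x) standardGeneric("satisfiedCount"))
#' @rdname accessors
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))
#' @rdname accessors
#' @export
setGeneric("productCounts", function(x) standardGeneric("productCounts"))
#' @rdname accessors
#' @export
setGeneric("productLedger", function(x) standardGeneric("productLedger"))

setMethod("bagRoot", "BDBag", function(x) x@root)
setMethod("payload", "BDBag", function(x) x@payload)
setMethod("remoteRefs", "BDBag", function(x) x@fetch)
setMethod("bagInfo", "BDBag", function(x) x@bagInfo)
setMethod("isHoley", "BDBag", function(x) any(!x@payload$present))
setMethod("isComplete", "BDBag", function(x) all(x@payload$present))

setMethod("isComplete", "BagValidation", function(x) x@complete)
setMethod("isValid", "BagValidation", function(x) {
  isTRUE(x@structuralOK) && isTRUE(x@complete) &&
    nrow(x@fixityErrors) == 0L && length(x@extraFiles) == 0L
})
setMethod("fixityErrors", "BagValidation", function(x) x@fixityErrors)
setMethod("missingEntries", "BagValidation", function(x) x@missingEntries)
setMethod("extraFiles", "BagValidation", function(x) x@extraFiles)

setMethod("satisfiedCount", "RubricResult", function(x) x@satisfiedCount)
setMethod("verdicts", "RubricResult", function(x) x@verdicts)

setMethod("productCounts", "PipelinePlan", function(x) x@counts)
setMethod("productLedger", "PipelinePlan", function(x) x@products)

setMethod("show", "BDBag", function(object) {
  state <- if (isComplete(object)) "complete" else "holey"
  cat(sprintf("BDBag (%s) at %s\n", state, object@root))
  cat(sprintf("  payload: %d entries (%d local, %d remote), %s bytes\n",
              nrow(object@payload), sum(object@payload$present),
              sum(!object@payload$present),
              format(sum(object@payload$size_bytes, na.rm = TRUE),
                     big.mark = ",")))
  cat(sprintf("  algorithms: %s\n", paste(object@algorithms, collapse = ", ")))
  if (!is.null(object@roManifest)) cat("  Research Object manifest: yes\n")
})

setMethod("show", "BagValidation", function(object) {
  verdict <- if (isValid(object)) "valid"
  else if (isTRUE(object@structuralOK)) "structurally valid but not valid"
  else "invalid"
  cat(sprintf("Bag validation (%s mode): %s\n", object@mode, verdict))
  cat(sprintf("  complete: %s; missing: %d; extra: %d; fixity errors: %d\n",
              object@complete, length(object@missingEntries),
              length(object@extraFiles), nrow(object@fixityErrors)))
  if (!is.na(object@oxumOK) && !object@oxumOK)
    cat(sprintf("  Payload-Oxum: %s\n", object@oxumReason))
})

setMethod("show", "IdentifierRecord", function(object) {
  cat(sprintf("<%s> %s (%s)\n", object@curie, object@title, object@status))
  cat(sprintf("  creator: %s, created: %s\n", object@creator, object@created))
  cat(sprintf("  %s: %s\n", object@checksumAlgorithm, object@checksum))
  cat(sprintf("  locations (%d): %s\n", length(object@locations),
              paste(object@locations, collapse = ", ")))
})

setMethod("show", "MinidRegistry", function(object) {
  n <- length(unique(vapply(readRegistryLines(object), `[[`, "", "curie")))
  cat(sprintf("Identifier registry '%s:' at %s (%d records)\n",
              object@prefix, object@path, n))
})

setMethod("show", "RubricResult", function(object) {
  cat(sprintf("FAIR rubric: %s satisfies %d/16 criteria\n",
              object@resource, object@satisfiedCount))
  marks <- ifelse(object@verdicts, "+", "-")
  cat(paste(sprintf("  [%s] %s", marks, names(object@verdicts)),
            collapse = "\n"), "\n")
})

setMethod("show", "PipelinePlan", function(object) {
  cat(sprintf("Pipeline plan: %d tissues x seeds {%s} x methods {%s}\n",
              length(object@tissues),
              paste(object@seeds, collapse = ","),
              paste(object@methods, collapse = ",")))
  for (nm in names(object@counts))
    cat(sprintf("  %s: %d\n", nm, object@counts[[nm]]))
})

setMethod("show", "FetchPlan", function(object) {
  cat(sprintf("Fetch plan for %s: %d entries (%d unavailable)\n",
              object@bagRoot, length(object@entries),
              sum(vapply(object@entries, `[[`, "", "status") == "unavailable")))
})

setMethod("show", "FetchResult", function(object) {
  tab <- table(object@outcomes$status)
  cat(sprintf("Fetch result: %s; %s bytes fetched\n",
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", "),
              format(object@bytesFetched, big.mark = ",")))
})
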