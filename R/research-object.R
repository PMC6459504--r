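RO_CONTEXT <- c("https://w3id.org/bundle/context")

## crude media-type guess for aggregate records
guessMediaType <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  types <- c(fastq = "application/fastq", bam = "application/bam",
             bed = "text/tab-separated-values",
             tsv = "text/tab-separated-values", txt = "text/plain",
             json = "application/json", zip = "application/zip",
             tgz = "application/gzip")
  unname(types[ext])
}

emptyAggregatesDF <- function() {
  data.frame(uri = character(), mediatype = character(),
             bundledAs = character(), stringsAsFactors = FALSE)
}

emptyAnnotationsDF <- function() {
  data.frame(about = character(), content = character(),
             stringsAsFactors = FALSE)
}

## targets an annotation may be "about": the bag itself, an aggregated
## bag-relative path, or an aggregated remote locator
resolveAnnotationTarget <- function(bag, about) {
  if (identical(about, "bag") || identical(about, "../")) return("../")
  if (about %in% bag@payload$path) return(about)
  if (about %in% bag@fetch$locator) return(about)
  stop(fairbagError("consistency",
                    sprintf("annotation target '%s' is not the bag or an aggregated resource",
                            about)))
}

#' Build and embed a Research Object manifest
#'
#' Generates the JSON-LD manifest stored at \code{metadata/manifest.json}.
#' The aggregates enumerate every payload entry (as a bag-relative path) and
#' every remote reference (as its locator URI); annotations attach free
#' content to the bag or to individual aggregates. The manifest file is
#' itself a tag file, so tampering with the metadata is caught by
#' \code{\link{validateBag}} in full mode.
#'
#' @param bag a structurally valid \linkS4class{BDBag}.
#' @param createdBy list with \code{name} and optional \code{uri}.
#' @param annotations list of \code{list(about=, content=)} records, where
#'   \code{about} is \code{"bag"}, a payload path, or a remote locator.
#' @param createdOn optional RFC 3339 timestamp override (UTC, second
#'   precision) for reproducible serialization.
#' @return the updated \linkS4class{BDBag} carrying the manifest.
#' @export
buildRoManifest <- function(bag, createdBy = list(name = "fairbag"),
                            annotations = list(), createdOn = NULL) {
  stopifnot(is(bag, "BDBag"))
  rep <- validateBag(bag, mode = "structural")
  if (!rep@structuralOK) {
    stop(fairbagError("input", "bag is not structurally valid"))
  }
  local <- bag@payload[bag@payload$present & !(bag@payload$path %in% bag@fetch$path), ,
                       drop = FALSE]
  agg <- rbind(
    if (nrow(local)) data.frame(uri = local$path,
                                mediatype = vapply(local$path, function(p) {
                                  mt <- guessMediaType(p)
                                  if (length(mt)) mt else NA_character_
                                }, NA_character_, USE.NAMES = FALSE),
                                bundledAs = NA_character_,
                                stringsAsFactors = FALSE),
    if (nrow(bag@fetch)) data.frame(uri = bag@fetch$locator,
                                    mediatype = NA_character_,
                                    bundledAs = bag@fetch$path,
                                    stringsAsFactors = FALSE)
  )
  if (is.null(agg)) agg <- emptyAggregatesDF()

  ann <- emptyAnnotationsDF()
  for (a in annotations) {
    ann <- rbind(ann, data.frame(about = resolveAnnotationTarget(bag, a$about),
                                 content = a$content, stringsAsFactors = FALSE))
  }

  ro <- new("RoManifest", context = RO_CONTEXT,
            createdOn = if (is.null(createdOn)) rfc3339Now() else createdOn,
            createdBy = createdBy, aggregates = agg, annotations = ann)
  bag@roManifest <- ro
  flushBag(bag)
}

writeRoManifestFile <- function(ro, path) {
  aggList <- lapply(seq_len(nrow(ro@aggregates)), function(i) {
    r <- as.list(ro@aggregates[i, ])
    r[!vapply(r, is.na, TRUE)]
  })
  annList <- lapply(seq_len(nrow(ro@annotations)), function(i)
    as.list(ro@annotations[i, ]))
  doc <- list(`@context` = as.list(ro@context),
              createdOn = ro@createdOn,
              createdBy = ro@createdBy,
              aggregates = aggList,
              annotations = annList)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

readRoManifestFile <- function(path) {
  doc <- jsonlite::read_json(path)
  agg <- emptyAggregatesDF()
  for (a in doc$aggregates) {
    agg <- rbind(agg, data.frame(
      uri = a$uri,
      mediatype = if (is.null(a$mediatype)) NA_character_ else a$mediatype,
      bundledAs = if (is.null(a$bundledAs)) NA_character_ else a$bundledAs,
      stringsAsFactors = FALSE))
  }
  ann <- emptyAnnotationsDF()
  for (a in doc$annotations) {
    ann <- rbind(ann, data.frame(about = a$about, content = a$content,
                                 stringsAsFactors = FALSE))
  }
  new("RoManifest", context = unlist(doc$`@context`),
      createdOn = doc$createdOn,
      createdBy = doc$createdBy, aggregates = agg, annotations = ann)
}

#' Check that a bag and its Research Object manifest agree
#'
#' @param bag a \linkS4class{BDBag} with an embedded manifest.
#' @return a character vector of inconsistencies; empty iff the manifest's
#'   aggregates, the payload, and the remote references are mutually
#'   consistent.
#' @export
checkAggregationConsistency <- function(bag) {
  stopifnot(is(bag, "BDBag"))
  if (is.null(bag@roManifest)) {
    stop(fairbagError("absent_metadata", "bag has no Research Object manifest"))
  }
  ro <- bag@roManifest
  issues <- character()
  pathAgg <- ro@aggregates$uri[!isCurie(ro@aggregates$uri) & !isUrl(ro@aggregates$uri)]
  uriAgg <- setdiff(ro@aggregates$uri, pathAgg)
  for (p in pathAgg) {
    if (!p %in% bag@payload$path) {
      issues <- c(issues, sprintf("aggregate '%s' has no payload entry", p))
    } else if (!file.exists(file.path(bag@root, p)) && !(p %in% bag@fetch$path)) {
      issues <- c(issues, sprintf("aggregate '%s' points to a deleted payload file", p))
    }
  }
  for (u in uriAgg) {
    if (!u %in% bag@fetch$locator) {
      issues <- c(issues, sprintf("aggregate '%s' has no remote reference", u))
    }
  }
  local <- bag@payload$path[!(bag@payload$path %in% bag@fetch$path)]
  for (p in setdiff(local, pathAgg)) {
    issues <- c(issues, sprintf("unaggregated entry '%s'", p))
  }
  for (l in setdiff(bag@fetch$locator, uriAgg)) {
    issues <- c(issues, sprintf("unaggregated remote reference '%s'", l))
  }
  for (a in ro@annotations$about) {
    if (!identical(a, "../") && !a %in% ro@aggregates$uri) {
      issues <- c(issues, sprintf("annotation about non-aggregated target '%s'", a))
    }
  }
  issues
}

#' Attach an annotation to a bag
#'
#' File content is copied under \code{metadata/annotations/} and covered by
#' the tag manifests; text content is written there as a file. The
#' annotation target must be the bag itself (\code{"bag"}), a payload path,
#' or a remote locator.
#'
#' @param bag a \linkS4class{BDBag} (an RO manifest is created if absent).
#' @param about annotation target.
#' @param content a path to an existing file, a URI, or free text.
#' @param name file name to store the content under; derived from
#'   \code{content} when omitted.
#' @return the updated \linkS4class{BDBag}.
#' @export
attachAnnotation <- function(bag, about, content, name = NULL) {
  stopifnot(is(bag, "BDBag"))
  if (is.null(bag@roManifest)) bag <- buildRoManifest(bag)
  target <- resolveAnnotationTarget(bag, about)

  if (file.exists(content) && !dir.exists(content)) {
    if (is.null(name)) name <- basename(content)
    annDir <- file.path(bag@root, "metadata", "annotations")
    dir.create(annDir, recursive = TRUE, showWarnings = FALSE)
    file.copy(content, file.path(annDir, name), overwrite = TRUE)
    ref <- paste0("metadata/annotations/", name)
  } else if (isUrl(content) || isCurie(content)) {
    ref <- content
  } else {
    if (is.null(name)) name <- sprintf("note-%d.txt", nrow(bag@roManifest@annotations) + 1L)
    annDir <- file.path(bag@root, "metadata", "annotations")
    dir.create(annDir, recursive = TRUE, showWarnings = FALSE)
    writeLinesUTF8(content, file.path(annDir, name))
    ref <- paste0("metadata/annotations/", name)
  }

  ro <- bag@roManifest
  ro@annotations <- rbind(ro@annotations,
                          data.frame(about = target, content = ref,
                                     stringsAsFactors = FALSE))
  bag@roManifest <- ro
  flushBag(bag)
}
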