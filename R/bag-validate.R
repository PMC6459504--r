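#' Validate a bag
#'
#' Three modes of increasing cost. \code{structural} checks the layout only:
#' declaration present, at least one payload manifest, every file under
#' \code{data/} enumerated, every tag file covered by the tag manifests, and
#' fetch entries consistent with the payload. \code{fast} adds a
#' Payload-Oxum check (octet count and stream count over local \emph{and}
#' remote entries; unknown remote lengths make the Oxum unverifiable).
#' \code{full} additionally recomputes every digest recorded for locally
#' present payload and tag files, so any single-byte modification is
#' reported as a fixity error.
#'
#' A holey bag is \emph{structurally valid but incomplete}: its unfetched
#' remote targets appear in \code{missingEntries} and \code{isComplete} is
#' \code{FALSE}, while \code{structuralOK} remains \code{TRUE}.
#'
#' @param bag a \linkS4class{BDBag}, or a path accepted by
#'   \code{\link{readBag}}.
#' @param mode one of "full", "fast", "structural".
#' @return a \linkS4class{BagValidation} report; no condition is ever
#'   signalled for findings, they are all collected in the report.
#' @export
validateBag <- function(bag, mode = c("full", "fast", "structural")) {
  mode <- match.arg(mode)
  if (!is(bag, "BDBag")) bag <- readBag(bag)
  root <- bag@root

  structuralOK <- TRUE
  pl <- bag@payload

  ## enumeration: data/ contents vs payload manifests
  onDisk <- listFilesRel(root)
  dataFiles <- onDisk[startsWith(onDisk, "data/")]
  extra <- setdiff(dataFiles, pl$path)
  missing <- pl$path[!file.exists(file.path(root, pl$path))]

  ## tag coverage: every non-payload file listed in the tag manifests
  tagOnDisk <- onDisk[!startsWith(onDisk, "data/") &
                        !grepl("^tagmanifest-[^/]+\\.txt$", onDisk)]
  extra <- c(extra, setdiff(tagOnDisk, bag@tagFiles$path))
  if (nrow(bag@tagFiles) == 0L && length(tagOnDisk)) structuralOK <- FALSE

  ## fetch consistency
  if (nrow(bag@fetch)) {
    if (!all(bag@fetch$path %in% pl$path)) structuralOK <- FALSE
    if (anyDuplicated(bag@fetch$path)) structuralOK <- FALSE
  }

  complete <- length(missing) == 0L

  oxumOK <- NA
  oxumReason <- character()
  if (mode %in% c("fast", "full")) {
    declared <- bag@bagInfo[["Payload-Oxum"]]
    if (is.null(declared)) {
      oxumOK <- FALSE
      oxumReason <- "no Payload-Oxum in bag-info.txt"
    } else if (nrow(bag@fetch) && anyNA(bag@fetch$length_bytes)) {
      oxumOK <- FALSE
      oxumReason <- "unverifiable: remote entries with unknown length"
    } else {
      presentPaths <- pl$path[file.exists(file.path(root, pl$path))]
      octets <- sum(file.size(file.path(root, presentPaths))) +
        sum(bag@fetch$length_bytes[!(bag@fetch$path %in% presentPaths)])
      observed <- sprintf("%.0f.%d", octets, nrow(pl))
      oxumOK <- identical(observed, declared)
      if (!oxumOK) {
        oxumReason <- sprintf("declared %s, observed %s", declared, observed)
      }
    }
  }

  fix <- data.frame(path = character(), algorithm = character(),
                    expected = character(), observed = character(),
                    stringsAsFactors = FALSE)
  if (mode == "full") {
    checkOne <- function(path, algorithm, expected) {
      observed <- fileDigest(file.path(root, path), algorithm)
      if (!identical(observed, expected)) {
        data.frame(path = path, algorithm = algorithm, expected = expected,
                   observed = observed, stringsAsFactors = FALSE)
      }
    }
    rows <- list()
    for (a in intersect(bag@algorithms, names(pl))) {
      idx <- which(!is.na(pl[[a]]) & file.exists(file.path(root, pl$path)))
      for (i in idx) rows <- c(rows, list(checkOne(pl$path[i], a, pl[[a]][i])))
    }
    tf <- bag@tagFiles
    for (a in setdiff(names(tf), "path")) {
      idx <- which(!is.na(tf[[a]]) & file.exists(file.path(root, tf$path)))
      for (i in idx) rows <- c(rows, list(checkOne(tf$path[i], a, tf[[a]][i])))
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) fix <- do.call(rbind, rows)
  }

  new("BagValidation", structuralOK = structuralOK, complete = complete,
      fixityErrors = fix, missingEntries = missing,
      extraFiles = unique(extra), oxumOK = oxumOK, oxumReason = oxumReason,
      mode = mode)
}
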