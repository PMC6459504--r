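## Tag-file serialization. All tag files use LF line endings and UTF-8, and
## manifests are sorted byte-lexicographically so a bag serializes
## identically regardless of platform or locale.

payloadOxum <- function(bag) {
  octets <- sum(bag@payload$size_bytes, na.rm = TRUE)
  sprintf("%.0f.%d", octets, nrow(bag@payload))
}

manifestFileName <- function(algorithm, tag = FALSE) {
  sprintf("%smanifest-%s.txt", if (tag) "tag" else "", algorithm)
}

writeManifestFile <- function(path, entries) {
  ord <- order(entries$path, method = "radix")
  writeLinesUTF8(sprintf("%s  %s", entries$digest[ord], entries$path[ord]), path)
}

## Rewrite every tag file of the bag at its root so that the on-disk state
## mirrors the in-memory object. Returns the bag with refreshed tagFiles.
flushBag <- function(bag) {
  root <- bag@root
  writeLinesUTF8(c(sprintf("BagIt-Version: %s", bag@version),
                   sprintf("Tag-File-Character-Encoding: %s", bag@encoding)),
                 file.path(root, "bagit.txt"))

  for (a in bag@algorithms) {
    keep <- !is.na(bag@payload[[a]])
    writeManifestFile(file.path(root, manifestFileName(a)),
                      data.frame(digest = bag@payload[[a]][keep],
                                 path = bag@payload$path[keep]))
  }

  fetchPath <- file.path(root, "fetch.txt")
  if (nrow(bag@fetch)) {
    len <- ifelse(is.na(bag@fetch$length_bytes), "-",
                  sprintf("%.0f", bag@fetch$length_bytes))
    writeLinesUTF8(sprintf("%s %s %s", bag@fetch$locator, len,
                           encodeFetchPath(bag@fetch$path)), fetchPath)
  } else if (file.exists(fetchPath)) {
    unlink(fetchPath)
  }

  bag@bagInfo["Payload-Oxum"] <- payloadOxum(bag)
  writeLinesUTF8(sprintf("%s: %s", names(bag@bagInfo), bag@bagInfo),
                 file.path(root, "bag-info.txt"))

  if (!is.null(bag@roManifest)) {
    dir.create(file.path(root, "metadata"), showWarnings = FALSE)
    writeRoManifestFile(bag@roManifest, file.path(root, "metadata", "manifest.json"))
  }

  ## tag manifests cover every non-payload file except themselves
  all <- listFilesRel(root)
  tagPaths <- all[!startsWith(all, "data/") &
                    !grepl("^tagmanifest-[^/]+\\.txt$", all)]
  tf <- data.frame(path = tagPaths, stringsAsFactors = FALSE)
  for (a in bag@algorithms) {
    tf[[a]] <- vapply(file.path(root, tagPaths), fileDigest, "", algorithm = a,
                      USE.NAMES = FALSE)
    writeManifestFile(file.path(root, manifestFileName(a, tag = TRUE)),
                      data.frame(digest = tf[[a]], path = tf$path))
  }
  bag@tagFiles <- tf
  bag
}

#' Serialize a bag
#'
#' \code{layout = "directory"} rewrites the bag's tag files in place and
#' returns its root. The archive layouts produce a zip or gzipped tar file
#' containing a single top-level directory named after the bag, as expected
#' by \code{\link{readBag}} and by recursive bag-of-bags materialization.
#'
#' @param bag a \linkS4class{BDBag}.
#' @param layout one of "directory", "zip", "tgz".
#' @param dest destination archive path; defaults to the bag root plus
#'   ".zip"/".tgz". Ignored for the directory layout.
#' @return the serialized location, invisibly for "directory".
#' @export
writeBag <- function(bag, layout = c("directory", "zip", "tgz"), dest = NULL) {
  stopifnot(is(bag, "BDBag"))
  layout <- match.arg(layout)
  bag <- flushBag(bag)
  if (layout == "directory") return(invisible(bag@root))
  if (is.null(dest)) dest <- paste0(bag@root, ".", layout)
  if (!dir.exists(dirname(dest))) {
    stop(fairbagError("io", sprintf("unwritable destination '%s'", dest)))
  }
  dest <- file.path(normalizePath(dirname(dest)), basename(dest))
  if (layout == "zip") {
    zip::zip(dest, files = basename(bag@root), root = dirname(bag@root),
             mode = "mirror")
  } else {
    withr::with_dir(dirname(bag@root),
      utils::tar(dest, files = basename(bag@root), compression = "gzip",
                 tar = "internal"))
  }
  dest
}

unpackArchive <- function(location, exdir = tempfile("bag-")) {
  dir.create(exdir, recursive = TRUE)
  if (grepl("\\.zip$", location)) {
    utils::unzip(location, exdir = exdir)
  } else if (grepl("\\.(tgz|tar\\.gz)$", location)) {
    utils::untar(location, exdir = exdir)
  } else {
    stop(fairbagError("input",
                      sprintf("'%s' is neither a directory nor a known archive",
                              location)))
  }
  tops <- list.files(exdir, full.names = TRUE)
  tops <- tops[dir.exists(tops)]
  if (length(tops) != 1L) {
    stop(fairbagError("not_a_bag",
                      "archive must contain exactly one top-level bag directory"))
  }
  tops
}

parseManifestLines <- function(lines, path) {
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([0-9a-fA-F]+)\\s+(.+)$", lines))
  bad <- which(vapply(m, length, 0L) != 3L)
  if (length(bad)) {
    stop(fairbagError("parse",
                      sprintf("malformed manifest line %d in %s", bad[1], path)))
  }
  data.frame(digest = tolower(vapply(m, `[`, "", 2)),
             path = vapply(m, `[`, "", 3), stringsAsFactors = FALSE)
}

parseFetchLines <- function(lines) {
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^(\\S+) (\\S+) (.+)$", lines))
  bad <- which(vapply(m, length, 0L) != 4L)
  if (length(bad)) {
    stop(fairbagError("parse",
                      sprintf("malformed fetch.txt line %d", bad[1])))
  }
  len <- vapply(m, `[`, "", 3)
  badLen <- which(len != "-" & !grepl("^[0-9]+$", len))
  if (length(badLen)) {
    stop(fairbagError("parse",
                      sprintf("malformed fetch.txt line %d: length must be a decimal integer or '-'",
                              badLen[1])))
  }
  data.frame(locator = vapply(m, `[`, "", 2),
             length_bytes = ifelse(len == "-", NA_real_, as.numeric(len)),
             path = decodeFetchPath(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

parseBagInfoLines <- function(lines) {
  pairs <- character()
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^\\s", ln) && length(pairs)) {
      pairs[length(pairs)] <- paste0(pairs[length(pairs)], " ", trimws(ln))
    } else {
      m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) {
        stop(fairbagError("parse", sprintf("malformed bag-info.txt line: '%s'", ln)))
      }
      pairs[m[2]] <- m[3]
    }
  }
  pairs
}

#' Read a bag from a directory or archive
#'
#' Parses the declaration, payload and tag manifests, \code{fetch.txt},
#' \code{bag-info.txt} and the Research Object manifest (when present) into
#' a \linkS4class{BDBag}. Tag files the package does not recognize are left
#' untouched on disk and remain covered by the tag manifests.
#'
#' @param location bag directory, or a \code{.zip}/\code{.tgz} archive
#'   containing one top-level bag directory (extracted to a temporary
#'   location).
#' @return a \linkS4class{BDBag}.
#' @export
readBag <- function(location) {
  if (!file.exists(location)) {
    stop(fairbagError("input", sprintf("'%s' does not exist", location)))
  }
  root <- if (dir.exists(location)) normalizePath(location)
          else unpackArchive(location)

  bagitPath <- file.path(root, "bagit.txt")
  if (!file.exists(bagitPath)) {
    stop(fairbagError("not_a_bag",
                      sprintf("'%s' is not a bag: no bagit.txt", root)))
  }
  decl <- parseBagInfoLines(readLinesUTF8(bagitPath))
  version <- decl[["BagIt-Version"]]
  encoding <- decl[["Tag-File-Character-Encoding"]]
  if (is.null(version) || is.null(encoding)) {
    stop(fairbagError("not_a_bag", "malformed bagit.txt declaration"))
  }

  manifestFiles <- list.files(root, pattern = "^manifest-[^/]+\\.txt$")
  if (length(manifestFiles) == 0L) {
    stop(fairbagError("not_a_bag",
                      sprintf("'%s' is not a bag: no payload manifest files", root)))
  }
  algorithms <- sub("^manifest-(.+)\\.txt$", "\\1", manifestFiles)
  manifests <- lapply(manifestFiles, function(f)
    parseManifestLines(readLinesUTF8(file.path(root, f)), f))
  names(manifests) <- algorithms

  fetchPath <- file.path(root, "fetch.txt")
  fetch <- if (file.exists(fetchPath))
    parseFetchLines(readLinesUTF8(fetchPath)) else emptyFetchDF()

  paths <- lexSort(unique(unlist(lapply(manifests, `[[`, "path"))))
  present <- file.exists(file.path(root, paths))
  sizes <- ifelse(present, as.numeric(file.size(file.path(root, paths))),
                  fetch$length_bytes[match(paths, fetch$path)])
  pl <- data.frame(path = paths, size_bytes = sizes, present = present,
                   stringsAsFactors = FALSE)
  for (a in algorithms) {
    pl[[a]] <- manifests[[a]]$digest[match(paths, manifests[[a]]$path)]
  }

  infoPath <- file.path(root, "bag-info.txt")
  info <- if (file.exists(infoPath)) parseBagInfoLines(readLinesUTF8(infoPath))
          else character()

  tagManifestFiles <- list.files(root, pattern = "^tagmanifest-[^/]+\\.txt$")
  tf <- data.frame(path = character(), stringsAsFactors = FALSE)
  for (f in tagManifestFiles) {
    a <- sub("^tagmanifest-(.+)\\.txt$", "\\1", f)
    tm <- parseManifestLines(readLinesUTF8(file.path(root, f)), f)
    tf <- merge(tf, stats::setNames(tm, c(a, "path")), by = "path", all = TRUE)
  }

  roPath <- file.path(root, "metadata", "manifest.json")
  ro <- if (file.exists(roPath)) readRoManifestFile(roPath) else NULL

  new("BDBag", root = root, version = version, encoding = encoding,
      algorithms = algorithms, payload = pl, fetch = fetch, bagInfo = info,
      tagFiles = tf, roManifest = ro)
}
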