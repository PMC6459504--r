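#' Create a BDBag from a directory tree
#'
#' Converts \code{dir} into a BagIt 1.0 bag in place: every file in the tree
#' is moved under \code{data/}, preserving the relative hierarchy, and the
#' declaration, payload manifests, \code{bag-info.txt} and tag manifests are
#' written. The resulting bag is complete and valid by construction.
#'
#' @param dir directory to bag in place (may be empty).
#' @param info named character vector of extra \code{bag-info.txt} pairs
#'   (e.g. \code{External-Description}). \code{Bagging-Date} and
#'   \code{Payload-Oxum} are always set.
#' @param algorithms checksum algorithms for the payload and tag manifests;
#'   md5 and sha256 by default (ENCODE metadata supplies md5; the identifier
#'   registry binds sha256).
#' @param baggingDate optional override of the Bagging-Date value, for
#'   byte-reproducible bags.
#' @return a \linkS4class{BDBag}.
#' @examples
#' d <- file.path(tempdir(), "mybag")
#' dir.create(d)
#' writeLines("ACGT", file.path(d, "reads.txt"))
#' bag <- createBag(d)
#' isComplete(bag)
#' @export
createBag <- function(dir, info = character(),
                      algorithms = c("md5", "sha256"),
                      baggingDate = NULL) {
  if (!dir.exists(dir)) {
    stop(fairbagError("input", sprintf("source tree '%s' is not readable", dir)))
  }
  if (length(algorithms) == 0L) {
    stop(fairbagError("configuration", "at least one checksum algorithm required"))
  }
  bad <- setdiff(algorithms, SUPPORTED_ALGORITHMS)
  if (length(bad)) {
    stop(fairbagError("configuration",
                      sprintf("unsupported checksum algorithm '%s'", bad[1])))
  }
  dir <- normalizePath(dir, mustWork = TRUE)
  if (file.exists(file.path(dir, "bagit.txt"))) {
    stop(fairbagError("input", sprintf("'%s' is already a bag", dir)))
  }

  files <- listFilesRel(dir)
  unreadable <- files[file.access(file.path(dir, files), 4) != 0]
  if (length(unreadable)) {
    stop(fairbagError("input",
                      sprintf("unreadable file(s): %s",
                              paste(unreadable, collapse = ", "))))
  }

  ## move the tree under data/
  dataDir <- file.path(dir, "data")
  dir.create(dataDir, showWarnings = FALSE)
  for (f in files) {
    dest <- file.path(dataDir, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    if (!file.rename(file.path(dir, f), dest)) {
      file.copy(file.path(dir, f), dest)
      unlink(file.path(dir, f))
    }
  }
  ## drop now-empty original subdirectories
  subdirs <- list.dirs(dir, recursive = TRUE, full.names = TRUE)
  subdirs <- setdiff(subdirs, c(dir, dataDir, list.dirs(dataDir)))
  for (d in rev(subdirs)) if (length(list.files(d, all.files = TRUE, no.. = TRUE)) == 0) unlink(d, recursive = TRUE)

  paths <- if (length(files)) paste0("data/", files) else character()
  pl <- emptyPayloadDF(algorithms)
  if (length(paths)) {
    pl <- data.frame(path = paths,
                     size_bytes = as.numeric(file.size(file.path(dir, paths))),
                     present = TRUE, stringsAsFactors = FALSE)
    for (a in algorithms) {
      pl[[a]] <- vapply(file.path(dir, paths), fileDigest, "", algorithm = a,
                        USE.NAMES = FALSE)
    }
  }

  baseInfo <- c("Bag-Software-Agent" = "fairbag",
                "Bagging-Date" = if (is.null(baggingDate))
                  format(Sys.Date(), "%Y-%m-%d") else baggingDate)
  bagInfo <- c(info, baseInfo[setdiff(names(baseInfo), names(info))])

  bag <- new("BDBag", root = dir, version = "1.0", encoding = "UTF-8",
             algorithms = algorithms, payload = pl, fetch = emptyFetchDF(),
             bagInfo = bagInfo, tagFiles = data.frame(path = character()),
             roManifest = NULL)
  flushBag(bag)
}

#' Add a remote file reference to a bag
#'
#' Records a \code{fetch.txt} entry -- a (locator, length, target path)
#' triple -- and a non-present payload entry carrying the supplied digests,
#' making the bag \emph{holey}. The locator may be a plain URL or an
#' identifier CURIE (e.g. \code{"minid:b9q119"}), which the materializer
#' resolves through a registry to the record's storage locations.
#'
#' @param bag a \linkS4class{BDBag}.
#' @param locator URL or identifier CURIE of the remote bytes.
#' @param targetPath destination path under \code{data/}.
#' @param digests named character vector of expected digests, e.g.
#'   \code{c(md5 = "...")}; at least one is required, otherwise the fetched
#'   content could never be verified.
#' @param lengthBytes expected size in bytes, or \code{NA} if unknown.
#' @return the updated (holey) \linkS4class{BDBag}; tag files on disk are
#'   rewritten immediately.
#' @export
addRemoteReference <- function(bag, locator, targetPath, digests,
                               lengthBytes = NA_real_) {
  stopifnot(is(bag, "BDBag"))
  targetPath <- normalizeRelPath(targetPath)
  assertPayloadPath(targetPath)
  if (targetPath %in% bag@payload$path) {
    stop(fairbagError("conflict",
                      sprintf("payload entry '%s' already exists", targetPath)))
  }
  if (length(digests) == 0L || is.null(names(digests)) ||
      !any(nzchar(names(digests)))) {
    stop(fairbagError("input",
                      "at least one named digest is required for a remote reference"))
  }
  unknown <- setdiff(names(digests), SUPPORTED_ALGORITHMS)
  if (length(unknown)) {
    stop(fairbagError("configuration",
                      sprintf("unsupported checksum algorithm '%s'", unknown[1])))
  }
  ## digest algorithms not yet recorded in the bag gain a manifest
  newAlgs <- setdiff(names(digests), bag@algorithms)
  if (length(newAlgs)) {
    for (a in newAlgs) bag@payload[[a]] <- rep(NA_character_, nrow(bag@payload))
    bag@algorithms <- c(bag@algorithms, newAlgs)
  }
  row <- data.frame(path = targetPath,
                    size_bytes = as.numeric(lengthBytes),
                    present = FALSE, stringsAsFactors = FALSE)
  for (a in bag@algorithms) {
    row[[a]] <- if (a %in% names(digests)) tolower(digests[[a]]) else NA_character_
  }
  bag@payload <- rbind(bag@payload, row)
  bag@fetch <- rbind(bag@fetch,
                     data.frame(locator = locator,
                                length_bytes = as.numeric(lengthBytes),
                                path = targetPath, stringsAsFactors = FALSE))
  validObject(bag)
  flushBag(bag)
}
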