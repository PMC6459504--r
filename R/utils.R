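#' @importFrom digest digest
NULL

## Checksum algorithms the package knows how to compute. BagIt manifest file
## names are derived from these ("manifest-md5.txt", ...).
SUPPORTED_ALGORITHMS <- c("md5", "sha1", "sha256", "sha512")

fileDigest <- function(path, algorithm) {
  if (!algorithm %in% SUPPORTED_ALGORITHMS) {
    stop(fairbagError("configuration",
                      sprintf("unsupported checksum algorithm '%s'", algorithm)))
  }
  digest::digest(file = path, algo = algorithm, serialize = FALSE)
}

rawDigest <- function(bytes, algorithm) {
  digest::digest(bytes, algo = algorithm, serialize = FALSE)
}

## Classed conditions so callers can distinguish failure modes.
fairbagError <- function(class, message, ...) {
  structure(
    class = c(paste0("fairbag_", class, "_error"), "fairbag_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

## Stable lexicographic (byte-wise) ordering, independent of the locale, so
## that manifests serialize identically everywhere.
lexSort <- function(x) {
  withr::with_locale(c(LC_COLLATE = "C"), sort(x, method = "radix"))
}

## List all files below `dir` as relative paths with forward slashes.
listFilesRel <- function(dir) {
  files <- list.files(dir, recursive = TRUE, all.files = TRUE, no.. = TRUE,
                      full.names = FALSE)
  lexSort(files[!dir.exists(file.path(dir, files))])
}

## Normalize a payload path: forward slashes, no leading "./".
normalizeRelPath <- function(path) {
  path <- gsub("\\\\", "/", path)
  sub("^\\./", "", path)
}

assertPayloadPath <- function(path) {
  bad <- !startsWith(path, "data/") |
    vapply(strsplit(path, "/", fixed = TRUE),
           function(p) any(p %in% c("..", "")), logical(1))
  if (any(bad)) {
    stop(fairbagError("input",
                      sprintf("invalid payload path(s): %s",
                              paste(path[bad], collapse = ", "))))
  }
  invisible(path)
}

## fetch.txt dialect: "%", CR and LF in target paths are percent-encoded.
encodeFetchPath <- function(path) {
  path <- gsub("%", "%25", path, fixed = TRUE)
  path <- gsub("\r", "%0D", path, fixed = TRUE)
  gsub("\n", "%0A", path, fixed = TRUE)
}

decodeFetchPath <- function(path) {
  path <- gsub("%0A", "\n", path, fixed = TRUE)
  path <- gsub("%0D", "\r", path, fixed = TRUE)
  gsub("%25", "%", path, fixed = TRUE)
}

## Write lines with LF endings and no trailing-newline surprises.
writeLinesUTF8 <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) {
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

readLinesUTF8 <- function(path) {
  ## tolerate invalid byte sequences (e.g. tampered tag files) so that
  ## corruption is reported by fixity checks rather than as a read error
  iconv(readLines(path, encoding = "UTF-8", warn = FALSE),
        "UTF-8", "UTF-8", sub = "byte")
}

## RFC 3339 UTC timestamp at second precision; injectable for reproducible
## serialization in tests.
rfc3339Now <- function(time = Sys.time()) {
  format(as.POSIXct(time, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
}

isUrl <- function(x) {
  grepl("^(https?|file|ftp)://", x)
}

## CURIE = "prefix:suffix" that is not a URL.
isCurie <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9._-]*:[^/].*$", x) & !isUrl(x)
}

parseCurie <- function(curie) {
  if (length(curie) != 1L || !isCurie(curie)) {
    stop(fairbagError("parse", sprintf("malformed identifier CURIE: '%s'", curie)))
  }
  parts <- regmatches(curie, regexec("^([^:]+):(.+)$", curie))[[1]]
  list(prefix = parts[2], suffix = parts[3])
}

## Turn a free-text group label into a safe directory/file slug.
slugify <- function(x) {
  x <- tolower(gsub("[^A-Za-z0-9]+", "_", x))
  gsub("^_+|_+$", "", x)
}

pathFromFileUrl <- function(url) {
  sub("^file://", "", url)
}
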