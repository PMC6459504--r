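#' Default column mapping for ENCODE-portal metadata exports
#'
#' Maps internal field names to the column headers of an ENCODE portal
#' metadata TSV. Pass a modified copy to \code{\link{parseManifest}} when a
#' real export uses different headers.
#'
#' @return named character vector (internal field -> TSV column header).
#' @export
encodeColumnMap <- function() {
  c(file_accession = "File accession",
    experiment_accession = "Experiment accession",
    assay = "Assay",
    tissue = "Biosample term name",
    biosample_id = "Biosample accession",
    replicate_id = "Technical replicate",
    file_format = "File format",
    size_bytes = "Size",
    md5 = "md5sum",
    url = "File download URL")
}

#' Parse an ENCODE-style metadata table
#'
#' Reads a tab-separated metadata export (UTF-8, header row) into one
#' validated row per downloadable file. Parsing is strict: a missing
#' required column, a duplicated file accession, a non-integer size (e.g.
#' with thousands separators), a malformed md5, or an empty
#' tissue/biosample/replicate field is a format error naming the offending
#' column and line numbers -- silent coercion would poison the downstream
#' bookkeeping.
#'
#' @param tsv path to the TSV file.
#' @param columnMap header mapping, see \code{\link{encodeColumnMap}}.
#' @return data.frame of manifest rows with internal column names.
#' @export
parseManifest <- function(tsv, columnMap = encodeColumnMap()) {
  raw <- utils::read.delim(tsv, check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  missingCols <- setdiff(columnMap, names(raw))
  if (length(missingCols)) {
    stop(fairbagError("format",
                      sprintf("missing required column(s): %s",
                              paste(missingCols, collapse = ", "))))
  }
  rows <- stats::setNames(raw[, columnMap, drop = FALSE], names(columnMap))
  lineOf <- function(i) i + 1L  # header occupies line 1

  badSize <- which(!grepl("^[0-9]+$", rows$size_bytes))
  if (length(badSize)) {
    stop(fairbagError("format",
                      sprintf("column '%s': non-integer size on line(s) %s",
                              columnMap[["size_bytes"]],
                              paste(lineOf(badSize), collapse = ", "))))
  }
  badMd5 <- which(!grepl("^[0-9a-fA-F]{32}$", rows$md5))
  if (length(badMd5)) {
    stop(fairbagError("format",
                      sprintf("column '%s': malformed md5 on line(s) %s",
                              columnMap[["md5"]],
                              paste(lineOf(badMd5), collapse = ", "))))
  }
  for (f in c("tissue", "biosample_id", "replicate_id", "file_accession")) {
    empty <- which(!nzchar(trimws(rows[[f]])))
    if (length(empty)) {
      stop(fairbagError("format",
                        sprintf("column '%s': empty value on line(s) %s",
                                columnMap[[f]],
                                paste(lineOf(empty), collapse = ", "))))
    }
  }
  dup <- which(duplicated(rows$file_accession))
  if (length(dup)) {
    stop(fairbagError("format",
                      sprintf("duplicate file accession(s): %s",
                              paste(unique(rows$file_accession[dup]),
                                    collapse = ", "))))
  }
  rows$size_bytes <- as.numeric(rows$size_bytes)
  rows$md5 <- tolower(rows$md5)
  rows
}

#' Filter manifest rows by query predicates
#'
#' All supplied predicates must hold (conjunction); each accepts a vector
#' of admissible values. Row order is preserved and an empty result is
#' legal.
#'
#' @param rows manifest rows from \code{\link{parseManifest}}.
#' @param assay,tissue,file_format optional value sets.
#' @return the matching rows.
#' @export
filterRows <- function(rows, assay = NULL, tissue = NULL, file_format = NULL) {
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(assay)) keep <- keep & rows$assay %in% assay
  if (!is.null(tissue)) keep <- keep & rows$tissue %in% tissue
  if (!is.null(file_format)) keep <- keep & rows$file_format %in% file_format
  rows[keep, , drop = FALSE]
}

#' Summarize a manifest by group
#'
#' Per-group bookkeeping in the sense of the per-tissue dataset table:
#' distinct biosamples, distinct replicates (a replicate is a
#' (biosample, replicate) pair -- one replicate may span several files),
#' file count, and total bytes. Column sums are attached as a
#' \code{"totals"} attribute, retrievable with \code{\link{summaryTotals}}.
#'
#' @param rows manifest rows.
#' @param by grouping column, default \code{"tissue"}.
#' @return data.frame (group, n_biosamples, n_replicates, n_files,
#'   total_bytes), sorted by group.
#' @export
summarizeManifest <- function(rows, by = "tissue") {
  groups <- if (nrow(rows)) lexSort(unique(rows[[by]])) else character()
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- rows[rows[[by]] == g, , drop = FALSE]
    data.frame(group = g,
               n_biosamples = length(unique(sub$biosample_id)),
               n_replicates = nrow(unique(sub[, c("biosample_id", "replicate_id")])),
               n_files = nrow(sub),
               total_bytes = sum(sub$size_bytes),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(group = character(), n_biosamples = integer(),
                      n_replicates = integer(), n_files = integer(),
                      total_bytes = numeric(), stringsAsFactors = FALSE)
  }
  attr(out, "totals") <- list(n_biosamples = sum(out$n_biosamples),
                              n_replicates = sum(out$n_replicates),
                              n_files = sum(out$n_files),
                              total_bytes = sum(out$total_bytes))
  out
}

#' @rdname summarizeManifest
#' @param x a summary returned by \code{summarizeManifest}.
#' @export
summaryTotals <- function(x) attr(x, "totals")

targetPathFor <- function(rows) {
  paste0("data/", rows$file_accession, ".", tolower(rows$file_format))
}

#' Convert manifest rows into a holey bag with a minted identifier
#'
#' The converter stage: one fetch entry per file (URL, declared size,
#' \code{data/<accession>.<format>}), md5 digests recorded in the payload
#' manifest, the source rows and the query record embedded as annotations
#' (so the exact query and its result are preserved verbatim inside the
#' bag), the bag archived, and an identifier minted for the archive. The
#' bag stays small -- kilobytes of tag files -- however large the data it
#' references.
#'
#' @param rows nonempty manifest rows.
#' @param dir directory to create the bag in.
#' @param registry a \linkS4class{MinidRegistry}.
#' @param title landing-record title for the minted identifier.
#' @param query optional query record: list with e.g. \code{predicates},
#'   \code{executed_on}, \code{source}; stored verbatim as a JSON
#'   annotation.
#' @param creator landing-record creator.
#' @param seed,created,baggingDate determinism knobs passed through to
#'   minting and bag creation.
#' @return list with \code{bag} (the holey \linkS4class{BDBag}),
#'   \code{record} (the minted \linkS4class{IdentifierRecord}) and
#'   \code{archive} (path of the zip the identifier names).
#' @export
rowsToHoleyBag <- function(rows, dir, registry, title = "converted dataset",
                           query = NULL, creator = "fairbag", seed = NULL,
                           created = NULL, baggingDate = NULL) {
  if (nrow(rows) == 0L) {
    stop(fairbagError("input", "no manifest rows to convert"))
  }
  targets <- targetPathFor(rows)
  if (anyDuplicated(targets)) {
    stop(fairbagError("conflict",
                      sprintf("colliding target path(s): %s",
                              paste(unique(targets[duplicated(targets)]),
                                    collapse = ", "))))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bag <- createBag(dir, info = c("External-Description" = title),
                   baggingDate = baggingDate)
  for (i in seq_len(nrow(rows))) {
    bag <- addRemoteReference(bag, rows$url[i], targets[i],
                              digests = c(md5 = rows$md5[i]),
                              lengthBytes = rows$size_bytes[i])
  }

  rowsFile <- tempfile(fileext = ".tsv")
  utils::write.table(rows, rowsFile, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  bag <- buildRoManifest(bag, createdBy = list(name = creator),
                         createdOn = created)
  bag <- attachAnnotation(bag, "bag", rowsFile, name = "manifest-rows.tsv")
  if (!is.null(query)) {
    queryFile <- tempfile(fileext = ".json")
    jsonlite::write_json(query, queryFile, auto_unbox = TRUE, pretty = TRUE)
    bag <- attachAnnotation(bag, "bag", queryFile, name = "query-record.json")
  }

  archive <- writeBag(bag, layout = "zip")
  record <- mintMinid(registry, file = archive, title = title,
                      creator = creator,
                      locations = paste0("file://", archive),
                      seed = seed, created = created,
                      extra = list(content_type = "bag+zip"))
  list(bag = bag, record = record, archive = archive)
}

#' Partition a manifest and build one bag per group plus a bag of bags
#'
#' One holey bag (with its own minted identifier) per distinct value of the
#' grouping key, and an outer bag whose remote references are the per-group
#' identifiers -- a "bag of bags" that names the whole collection with a
#' single identifier while each group remains independently processable.
#'
#' @param rows nonempty manifest rows.
#' @param dir working directory; per-group bags are created in
#'   subdirectories named after the (slugified) group value.
#' @param registry a \linkS4class{MinidRegistry}.
#' @param key grouping column, default \code{"tissue"}.
#' @param query,seed,created,baggingDate as in \code{\link{rowsToHoleyBag}}.
#' @return list with \code{inner} (named list of per-group results) and
#'   \code{outer} (the bag-of-bags result).
#' @export
partitionAndBag <- function(rows, dir, registry, key = "tissue",
                            query = NULL, seed = NULL, created = NULL,
                            baggingDate = NULL) {
  if (nrow(rows) == 0L) {
    stop(fairbagError("input", "no manifest rows to partition"))
  }
  groups <- lexSort(unique(rows[[key]]))
  inner <- list()
  for (g in groups) {
    sub <- rows[rows[[key]] == g, , drop = FALSE]
    inner[[g]] <- rowsToHoleyBag(sub, file.path(dir, slugify(g)), registry,
                                 title = g, query = query, seed = seed,
                                 created = created, baggingDate = baggingDate)
  }

  outerDir <- file.path(dir, "bag-of-bags")
  dir.create(outerDir, recursive = TRUE, showWarnings = FALSE)
  outerBag <- createBag(outerDir,
                        info = c("External-Description" =
                                   sprintf("bag of %d bags by %s",
                                           length(groups), key)),
                        baggingDate = baggingDate)
  for (g in groups) {
    res <- inner[[g]]
    outerBag <- addRemoteReference(
      outerBag, res$record@curie,
      paste0("data/", slugify(g), ".zip"),
      digests = c(sha256 = res$record@checksum),
      lengthBytes = file.size(res$archive))
  }
  outerBag <- buildRoManifest(outerBag, createdBy = list(name = "fairbag"),
                              createdOn = created)
  outerArchive <- writeBag(outerBag, layout = "zip")
  outerRecord <- mintMinid(registry, file = outerArchive,
                           title = sprintf("bag of bags (%s)", key),
                           creator = "fairbag",
                           locations = paste0("file://", outerArchive),
                           seed = seed, created = created,
                           extra = list(content_type = "bag+zip"))
  list(inner = inner,
       outer = list(bag = outerBag, record = outerRecord,
                    archive = outerArchive))
}

#' Plan the pipeline fan-out
#'
#' Pure combinatorial bookkeeping of the footprinting pipeline's products:
#' one input bag per tissue; one alignment bag per \{tissue, seed\}; one
#' merged, sorted alignment (BAM) per \{biosample, seed\}; one footprint
#' file per \{tissue, seed, method\}; one candidate-TFBS file per footprint
#' file. The returned ledger maps every product to its input group,
#' serializable as a provenance document with \code{\link{planToJSON}}.
#'
#' @param summaries per-tissue summary from \code{\link{summarizeManifest}}
#'   (the biosample counts drive the merged-alignment fan-out).
#' @param seeds nonempty alignment seed lengths, e.g. \code{c(16, 20)}.
#' @param methods nonempty footprinting method labels, e.g.
#'   \code{c("HINT", "WELLINGTON")}.
#' @return a \linkS4class{PipelinePlan}.
#' @export
planProducts <- function(summaries, seeds = c(16, 20),
                         methods = c("HINT", "WELLINGTON")) {
  if (length(seeds) == 0L || length(methods) == 0L) {
    stop(fairbagError("input", "seeds and methods must be nonempty"))
  }
  tissues <- summaries$group
  nBio <- stats::setNames(as.integer(summaries$n_biosamples), tissues)

  ledger <- list()
  add <- function(stage, product, tissue, seed = NA, method = NA, input) {
    ledger[[length(ledger) + 1L]] <<- data.frame(
      stage = stage, product = product, tissue = tissue,
      seed = seed, method = method, input = input, stringsAsFactors = FALSE)
  }
  for (t in tissues) {
    add("input", sprintf("input-bag/%s", slugify(t)), t,
        input = "metadata manifest")
    for (s in seeds) {
      add("alignment", sprintf("alignment-bag/%s/seed%d", slugify(t), s), t,
          seed = s, input = sprintf("input-bag/%s", slugify(t)))
      for (b in seq_len(nBio[[t]])) {
        add("merged_alignment",
            sprintf("merged-bam/%s/biosample%03d/seed%d", slugify(t), b, s),
            t, seed = s,
            input = sprintf("alignment-bag/%s/seed%d", slugify(t), s))
      }
      for (m in methods) {
        add("footprint",
            sprintf("footprints/%s/seed%d/%s", slugify(t), s, tolower(m)),
            t, seed = s, method = m,
            input = sprintf("alignment-bag/%s/seed%d", slugify(t), s))
        add("tfbs",
            sprintf("tfbs/%s/seed%d/%s", slugify(t), s, tolower(m)),
            t, seed = s, method = m,
            input = sprintf("footprints/%s/seed%d/%s", slugify(t), s,
                            tolower(m)))
      }
    }
  }
  products <- do.call(rbind, ledger)

  counts <- c(input_bags = as.numeric(length(tissues)),
              alignment_bags = as.numeric(length(tissues) * length(seeds)),
              merged_alignment_files = as.numeric(sum(nBio) * length(seeds)),
              footprint_files = as.numeric(length(tissues) * length(seeds) *
                                             length(methods)),
              tfbs_files = as.numeric(length(tissues) * length(seeds) *
                                        length(methods)))

  new("PipelinePlan", tissues = tissues, seeds = as.numeric(seeds),
      methods = methods, nBiosamples = nBio, counts = counts,
      products = products)
}

#' Serialize a pipeline plan as a JSON provenance ledger
#'
#' @param plan a \linkS4class{PipelinePlan}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
planToJSON <- function(plan, path) {
  doc <- list(tissues = plan@tissues, seeds = plan@seeds,
              methods = plan@methods,
              counts = as.list(plan@counts),
              products = plan@products)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}
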