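## Footprints and motif hits are plain data.frames in BED convention
## (0-based, half-open); GRanges (1-based, closed) is used internally for
## the overlap machinery, converting at the boundary.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

validateIntervals <- function(df, what, lines = NULL) {
  if (is.null(lines)) lines <- seq_len(nrow(df))
  bad <- which(!is.finite(df$start) | !is.finite(df$end))
  if (length(bad)) {
    stop(fairbagError("parse",
                      sprintf("%s: non-numeric coordinate on line(s) %s", what,
                              paste(lines[bad], collapse = ", "))))
  }
  empty <- which(df$start >= df$end)
  if (length(empty)) {
    stop(fairbagError("record",
                      sprintf("%s: empty or inverted interval on line(s) %s",
                              what, paste(lines[empty], collapse = ", "))))
  }
  noChrom <- which(!nzchar(df$chrom))
  if (length(noChrom)) {
    stop(fairbagError("record",
                      sprintf("%s: empty sequence name on line(s) %s", what,
                              paste(lines[noChrom], collapse = ", "))))
  }
  invisible(df)
}

#' Read a BED file of intervals
#'
#' Minimal strict BED reader: 3+ tab-separated columns, coordinates kept in
#' the 0-based half-open BED convention. Columns 4-6 are taken as name,
#' score, strand when present; further columns are preserved as
#' \code{extra1}, \code{extra2}, ... Records with \code{start >= end} or
#' non-numeric coordinates are rejected with their line numbers.
#'
#' @param file path to a BED file (no header).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   and any optional columns present.
#' @export
readBed <- function(file) {
  lines <- readLinesUTF8(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L)) {
    stop(fairbagError("parse",
                      sprintf("BED line(s) with fewer than 3 columns: %s",
                              paste(which(ncols < 3L), collapse = ", "))))
  }
  col <- function(i) vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  df <- data.frame(chrom = col(1),
                   start = suppressWarnings(as.numeric(col(2))),
                   end = suppressWarnings(as.numeric(col(3))),
                   stringsAsFactors = FALSE)
  extras <- c("name", "score", "strand")
  maxCol <- max(ncols)
  for (i in seq_len(maxCol - 3L)) {
    nm <- if (i <= 3L) extras[i] else sprintf("extra%d", i - 3L)
    df[[nm]] <- col(i + 3L)
  }
  validateIntervals(df, basename(file))
}

#' Write intervals as BED
#'
#' Tab-separated, LF-terminated, no header; numeric coordinates printed as
#' integers. Canonical files round-trip byte-identically through
#' \code{\link{readBed}}.
#'
#' @param df data.frame with at least chrom, start, end.
#' @param file destination path.
#' @return \code{file}, invisibly.
#' @export
writeBed <- function(df, file) {
  fmt <- function(x, coord) {
    out <- if (is.numeric(x) && coord) sprintf("%.0f", x)
           else if (is.numeric(x)) vapply(x, format, "", scientific = FALSE)
           else as.character(x)
    ifelse(is.na(x), ".", out)
  }
  cols <- Map(fmt, df, names(df) %in% c("start", "end"))
  writeLinesUTF8(if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character(),
                 file)
}

asGRanges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Intersect footprints with a motif-hit catalog
#'
#' Emits one candidate transcription-factor binding site per
#' (footprint, hit) pair sharing at least one base on the same sequence,
#' using GRanges overlap machinery. Strand is ignored for the overlap test
#' (hit strand is carried through); the overlap interval is the coordinate
#' intersection, so it is contained in both sources. Output is sorted by
#' (chrom, start, motif_id) with deterministic tie-breaking.
#'
#' @param footprints data.frame with chrom, start, end (0-based half-open)
#'   and optionally method, score.
#' @param hits data.frame with motif_id, chrom, start, end, strand,
#'   p_value, score.
#' @return data.frame of candidates: chrom, start, end, motif_id, strand,
#'   method, footprint_idx, hit_idx (row indices into the inputs).
#' @export
intersectCatalog <- function(footprints, hits) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), motif_id = character(),
                      strand = character(), method = character(),
                      footprint_idx = integer(), hit_idx = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(footprints) == 0L || nrow(hits) == 0L) return(empty)
  validateIntervals(footprints, "footprints")
  validateIntervals(hits, "hits")

  ## disjoint sequence sets are a legitimate empty result, not a warning
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(asGRanges(footprints), asGRanges(hits),
                                ignore.strand = TRUE))
  fi <- S4Vectors::queryHits(ov)
  hi <- S4Vectors::subjectHits(ov)
  if (length(fi) == 0L) return(empty)

  out <- data.frame(
    chrom = footprints$chrom[fi],
    start = pmax(footprints$start[fi], hits$start[hi]),
    end = pmin(footprints$end[fi], hits$end[hi]),
    motif_id = hits$motif_id[hi],
    strand = if ("strand" %in% names(hits)) hits$strand[hi] else ".",
    method = if ("method" %in% names(footprints)) footprints$method[fi]
             else NA_character_,
    footprint_idx = fi,
    hit_idx = hi,
    stringsAsFactors = FALSE)
  ord <- order(out$chrom, out$start, out$motif_id, out$end,
               out$footprint_idx, out$hit_idx, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidate TFBSs as BED6+
#'
#' chrom, start, end, name (the motif id), score (0), strand, then the
#' footprinting method and source row indices. Deterministically ordered,
#' so files are byte-stable.
#'
#' @param candidates output of \code{\link{intersectCatalog}}.
#' @param file destination path.
#' @return \code{file}, invisibly.
#' @export
writeCandidates <- function(candidates, file) {
  bed <- data.frame(chrom = candidates$chrom, start = candidates$start,
                    end = candidates$end, name = candidates$motif_id,
                    score = rep(0, nrow(candidates)),
                    strand = candidates$strand,
                    method = candidates$method,
                    footprint_idx = candidates$footprint_idx,
                    hit_idx = candidates$hit_idx,
                    stringsAsFactors = FALSE)
  writeBed(bed, file)
}

#' Intersect every footprint file of a materialized tree with a hit catalog
#'
#' Walks a directory tree of footprint BED files laid out as
#' \code{<tissue>/seed<k>/<method>.bed} (the shape produced by
#' materializing the footprint bag-of-bags), intersects each file
#' independently with the hit catalog, and writes one candidate file per
#' input. The per-\{tissue, seed\} outputs are bagged, each bag and the
#' enclosing bag of bags minted, closing the provenance loop for the final
#' dataset. An unreadable footprint file is recorded as a failure and the
#' run continues.
#'
#' @param footprintDir root of the footprint tree.
#' @param hits hit-catalog data.frame (see \code{\link{intersectCatalog}}).
#' @param outDir output directory for candidate files and bags.
#' @param registry a \linkS4class{MinidRegistry}.
#' @param seed,created,baggingDate determinism knobs for minting/bagging.
#' @return list with \code{files} (data.frame: tissue, seed, method, input,
#'   output, n_candidates, ok), \code{inner} (per-\{tissue,seed\} bag
#'   results) and \code{outer} (the minted bag-of-bags).
#' @export
intersectPerBag <- function(footprintDir, hits, outDir, registry,
                            seed = NULL, created = NULL, baggingDate = NULL) {
  beds <- list.files(footprintDir, pattern = "\\.bed$", recursive = TRUE)
  if (length(beds) == 0L) {
    stop(fairbagError("input", sprintf("no footprint BED files under '%s'",
                                       footprintDir)))
  }
  parts <- strsplit(beds, "/", fixed = TRUE)
  ok3 <- lengths(parts) == 3L
  if (!all(ok3)) {
    stop(fairbagError("input",
                      "footprint tree must be laid out as <tissue>/seed<k>/<method>.bed"))
  }
  files <- data.frame(
    tissue = vapply(parts, `[`, "", 1),
    seed = vapply(parts, `[`, "", 2),
    method = sub("\\.bed$", "", vapply(parts, `[`, "", 3)),
    input = file.path(footprintDir, beds),
    stringsAsFactors = FALSE)
  files <- files[order(files$tissue, files$seed, files$method,
                       method = "radix"), , drop = FALSE]

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files$output <- NA_character_
  files$n_candidates <- NA_integer_
  files$ok <- FALSE
  for (i in seq_len(nrow(files))) {
    res <- tryCatch({
      fp <- readBed(files$input[i])
      if (nrow(fp)) fp$method <- files$method[i]
      cand <- intersectCatalog(fp, hits)
      grpDir <- file.path(outDir, files$tissue[i], files$seed[i])
      dir.create(grpDir, recursive = TRUE, showWarnings = FALSE)
      out <- file.path(grpDir, paste0(files$method[i], ".bed"))
      writeCandidates(cand, out)
      list(output = out, n = nrow(cand))
    }, error = function(e) e)
    if (inherits(res, "error")) next
    files$output[i] <- res$output
    files$n_candidates[i] <- res$n
    files$ok[i] <- TRUE
  }

  ## bag each {tissue, seed} group, then mint a bag of bags over them
  groups <- unique(files[files$ok, c("tissue", "seed")])
  inner <- list()
  for (j in seq_len(nrow(groups))) {
    gdir <- file.path(outDir, groups$tissue[j], groups$seed[j])
    gbag <- createBag(gdir,
                      info = c("External-Description" =
                                 sprintf("candidate TFBSs, %s %s",
                                         groups$tissue[j], groups$seed[j])),
                      baggingDate = baggingDate)
    gbag <- buildRoManifest(gbag, createdOn = created)
    garchive <- writeBag(gbag, layout = "zip")
    grec <- mintMinid(registry, file = garchive,
                      title = sprintf("TFBS candidates %s/%s",
                                      groups$tissue[j], groups$seed[j]),
                      creator = "fairbag",
                      locations = paste0("file://", garchive),
                      seed = seed, created = created,
                      extra = list(content_type = "bag+zip"))
    inner[[paste(groups$tissue[j], groups$seed[j], sep = "/")]] <-
      list(bag = gbag, record = grec, archive = garchive)
    ## bagging moved the group's candidate files under data/
    idx <- files$ok & files$tissue == groups$tissue[j] &
      files$seed == groups$seed[j]
    files$output[idx] <- file.path(gdir, "data", basename(files$output[idx]))
  }

  outerDir <- file.path(outDir, "tfbs-bag-of-bags")
  dir.create(outerDir, recursive = TRUE, showWarnings = FALSE)
  outer <- createBag(outerDir,
                     info = c("External-Description" = "candidate TFBS bag of bags"),
                     baggingDate = baggingDate)
  for (nm in names(inner)) {
    res <- inner[[nm]]
    outer <- addRemoteReference(outer, res$record@curie,
                                paste0("data/", slugify(nm), ".zip"),
                                digests = c(sha256 = res$record@checksum),
                                lengthBytes = file.size(res$archive))
  }
  outer <- buildRoManifest(outer, createdOn = created)
  outerArchive <- writeBag(outer, layout = "zip")
  outerRecord <- mintMinid(registry, file = outerArchive,
                           title = "candidate TFBSs", creator = "fairbag",
                           locations = paste0("file://", outerArchive),
                           seed = seed, created = created,
                           extra = list(content_type = "bag+zip"))
  list(files = files,
       inner = inner,
       outer = list(bag = outer, record = outerRecord,
                    archive = outerArchive))
}
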