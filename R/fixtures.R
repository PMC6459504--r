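#' The 27-tissue study preset
#'
#' Per-tissue biosample and replicate counts of the DNase-seq corpus the
#' footprinting study extracted from ENCODE: 27 organ/tissue terms, 193
#' biosamples, 1,355 replicates. These counts are the conditions the
#' synthetic manifest generator emulates; they are inputs, not knobs.
#'
#' @return data.frame with columns \code{tissue}, \code{n_biosamples},
#'   \code{n_replicates}.
#' @export
table1Tissues <- function() {
  data.frame(
    tissue = c("adrenal gland", "blood vessel", "bone element", "brain",
               "bronchus", "esophagus", "extraembryonic", "eye",
               "gonad", "heart", "kidney", "large intestine", "liver",
               "lung", "lymphatic vessel", "lymphoblast", "mammary gland",
               "mouth", "muscle organ", "pancreas", "prostate gland",
               "skin", "spinal cord", "stomach", "thyroid gland",
               "tongue", "urinary bladder"),
    n_biosamples = c(3L, 10L, 1L, 29L, 2L, 2L, 11L, 8L, 2L, 8L, 8L, 5L, 3L,
                     7L, 2L, 21L, 2L, 4L, 4L, 2L, 2L, 48L, 2L, 1L, 3L, 2L,
                     1L),
    n_replicates = c(8L, 129L, 7L, 185L, 9L, 41L, 66L, 53L, 7L, 69L, 29L,
                     18L, 8L, 94L, 30L, 71L, 5L, 18L, 13L, 13L, 8L, 401L,
                     34L, 5L, 24L, 8L, 2L),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic manifest fixture
#'
#' @param seed integer driving all generated content; identical specs give
#'   byte-identical manifests and stores.
#' @param tissues data.frame like \code{\link{table1Tissues}} (the default,
#'   preset \code{"table1"}); pass a smaller table for quick fixtures.
#' @param sizeRange payload file size range in bytes. Generated files are
#'   deliberately small; the manifest's size column always reflects the
#'   actual bytes written so length checks stay meaningful.
#' @param assay,file_format manifest constants.
#' @return a list of class \code{fixtureSpec}.
#' @export
fixtureSpec <- function(seed = 1L, tissues = table1Tissues(),
                        sizeRange = c(1024L, 4096L), assay = "DNase-seq",
                        file_format = "fastq") {
  stopifnot(all(tissues$n_biosamples >= 1L),
            all(tissues$n_replicates >= tissues$n_biosamples))
  structure(list(seed = as.integer(seed), tissues = tissues,
                 sizeRange = as.integer(sizeRange), assay = assay,
                 file_format = file_format),
            class = "fixtureSpec")
}

#' Generate a synthetic ENCODE-style manifest and payload store
#'
#' Emulates a portal metadata export plus the files it points at, with no
#' network: one manifest row and one real payload file per replicate
#' (replicates are assigned round-robin to their tissue's biosamples, so
#' the per-tissue biosample and replicate counts of the spec are met
#' exactly), deterministic accessions, content drawn from the seeded RNG,
#' md5 values computed from the bytes actually written, and
#' \code{file://} URLs into the store.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory; the TSV is written to
#'   \code{<dir>/manifest.tsv} and payload files under \code{<dir>/store/}.
#' @return list with \code{tsv} and \code{store} paths.
#' @export
generateFixtureManifest <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  store <- file.path(normalizePath(dir), "store")
  dir.create(store, showWarnings = FALSE)
  tsv <- file.path(normalizePath(dir), "manifest.tsv")

  withr::with_seed(spec$seed, {
    rows <- list()
    fileNo <- 0L
    bioNo <- 0L
    for (t in seq_len(nrow(spec$tissues))) {
      tissue <- spec$tissues$tissue[t]
      nb <- spec$tissues$n_biosamples[t]
      nr <- spec$tissues$n_replicates[t]
      bios <- sprintf("ENCBS%05d", bioNo + seq_len(nb))
      expts <- sprintf("ENCSR%05d", bioNo + seq_len(nb))
      bioNo <- bioNo + nb
      repCounter <- integer(nb)
      for (r in seq_len(nr)) {
        b <- (r - 1L) %% nb + 1L
        repCounter[b] <- repCounter[b] + 1L
        fileNo <- fileNo + 1L
        acc <- sprintf("ENCFF%06d", fileNo)
        size <- sample(spec$sizeRange[1]:spec$sizeRange[2], 1L)
        bytes <- as.raw(sample(0:255, size, replace = TRUE))
        fn <- paste0(acc, ".", spec$file_format)
        writeBin(bytes, file.path(store, fn))
        rows[[fileNo]] <- data.frame(
          `File accession` = acc,
          `Experiment accession` = expts[b],
          `Assay` = spec$assay,
          `Biosample term name` = tissue,
          `Biosample accession` = bios[b],
          `Technical replicate` = sprintf("%d_1", repCounter[b]),
          `File format` = spec$file_format,
          `Size` = as.character(size),
          `md5sum` = rawDigest(bytes, "md5"),
          `File download URL` = paste0("file://", store, "/", fn),
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  list(tsv = tsv, store = store)
}

#' Generate seeded random footprints and motif hits
#'
#' Valid interval fixtures for the intersection stage: footprints 5-50 bp,
#' hits 6-20 bp, placed uniformly on the given chromosomes, hit p-values
#' uniform on (0, 1). Deterministic under the seed.
#'
#' @param nFootprints,nHits numbers of records (0 allowed).
#' @param chromSizes named integer vector of sequence lengths.
#' @param seed integer RNG seed.
#' @param methods footprint method labels, cycled across footprints.
#' @param motifs motif-id pool size for hits.
#' @return list with \code{footprints} and \code{hits} data.frames in
#'   0-based half-open coordinates.
#' @export
generateIntervals <- function(nFootprints, nHits,
                              chromSizes = c(chr1 = 1000000L, chr2 = 800000L),
                              seed = 1L, methods = c("HINT", "WELLINGTON"),
                              motifs = 25L) {
  stopifnot(nFootprints >= 0L, nHits >= 0L, length(chromSizes) >= 1L)
  withr::with_seed(seed, {
    mkIntervals <- function(n, minLen, maxLen) {
      if (n == 0L) {
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE))
      }
      chrom <- sample(names(chromSizes), n, replace = TRUE)
      len <- sample(minLen:maxLen, n, replace = TRUE)
      start <- vapply(seq_len(n), function(i)
        sample(0:(chromSizes[[chrom[i]]] - len[i]), 1L), numeric(1))
      data.frame(chrom = chrom, start = start, end = start + len,
                 stringsAsFactors = FALSE)
    }
    fp <- mkIntervals(nFootprints, 5L, 50L)
    if (nrow(fp)) {
      fp$method <- rep_len(methods, nrow(fp))
      fp$score <- round(stats::runif(nrow(fp), 1, 100), 2)
    }
    hits <- mkIntervals(nHits, 6L, 20L)
    if (nrow(hits)) {
      hits <- data.frame(motif_id = sprintf("MOTIF%04d",
                                            sample.int(motifs, nrow(hits),
                                                       replace = TRUE)),
                         hits,
                         strand = sample(c("+", "-"), nrow(hits),
                                         replace = TRUE),
                         p_value = stats::runif(nrow(hits)),
                         score = round(stats::runif(nrow(hits), 0, 30), 3),
                         stringsAsFactors = FALSE)
    } else {
      hits <- data.frame(motif_id = character(), hits,
                         strand = character(), p_value = numeric(),
                         score = numeric(), stringsAsFactors = FALSE)
    }
    list(footprints = fp, hits = hits)
  })
}

#' Generate a footprint file tree
#'
#' Lays out one BED file per \{tissue, seed length, method\} as
#' \code{<dir>/<tissue>/seed<k>/<method>.bed}, the shape
#' \code{\link{intersectPerBag}} consumes.
#'
#' @param dir output root.
#' @param tissues tissue labels (slugified for directory names).
#' @param seeds alignment seed lengths.
#' @param methods footprint method labels.
#' @param nPerFile footprints per file.
#' @param chromSizes sequence lengths for placement.
#' @param seed RNG seed.
#' @return character vector of the files written.
#' @export
generateFootprintTree <- function(dir, tissues, seeds = c(16L, 20L),
                                  methods = c("HINT", "WELLINGTON"),
                                  nPerFile = 20L,
                                  chromSizes = c(chr1 = 1000000L,
                                                 chr2 = 800000L),
                                  seed = 1L) {
  out <- character()
  k <- 0L
  for (t in tissues) for (s in seeds) for (m in methods) {
    k <- k + 1L
    sub <- generateIntervals(nPerFile, 0L, chromSizes,
                             seed = seed + k, methods = m)$footprints
    d <- file.path(dir, slugify(t), paste0("seed", s))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(d, paste0(tolower(m), ".bed"))
    writeBed(sub[, c("chrom", "start", "end", "method", "score")], f)
    out <- c(out, f)
  }
  out
}

#' Flip one byte of a file
#'
#' XORs the byte at \code{offset} with \code{0xFF}; applying the same
#' tamper twice restores the original bytes (XOR involution). Drives the
#' fixity-detection tests.
#'
#' @param path existing file.
#' @param offset 1-based byte position within the file.
#' @return \code{path}, invisibly.
#' @export
tamperFile <- function(path, offset = 1L) {
  if (!file.exists(path)) {
    stop(fairbagError("input", sprintf("'%s' does not exist", path)))
  }
  size <- file.size(path)
  if (offset < 1L || offset > size) {
    stop(fairbagError("input",
                      sprintf("offset %d outside file of %d bytes", offset,
                              size)))
  }
  bytes <- readBin(path, "raw", n = size)
  bytes[offset] <- xor(bytes[offset], as.raw(0xFF))
  writeBin(bytes, path)
  invisible(path)
}
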