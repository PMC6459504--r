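test_that("the BED reader keeps half-open coordinates and rejects bad records", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tfpA\t12.5\t+",
               "chr1\t250\t300\tfpB\t3.0\t-",
               "chr2\t0\t50\tfpC\t7.1\t+",
               "chr2\t75\t80\tfpD\t1.0\t-"), f)
  bed <- readBed(f)
  expect_identical(nrow(bed), 4L)
  expect_identical(bed$start[1], 100)
  expect_identical(bed$end[1], 200)

  # canonical files round-trip byte-identically
  out <- withr::local_tempfile(fileext = ".bed")
  writeBed(bed, out)
  expect_identical(readLines(out), readLines(f))

  writeLines("chr1\t100\t100\tx", f)
  expect_error(readBed(f), class = "fairbag_record_error")
  writeLines("chr1\tabc\t200", f)
  err <- tryCatch(readBed(f), error = identity)
  expect_s3_class(err, "fairbag_parse_error")
  expect_match(conditionMessage(err), "line")
  writeLines("chr1\t100", f)
  expect_error(readBed(f), class = "fairbag_parse_error")

  writeLines(character(), f)
  expect_identical(nrow(readBed(f)), 0L)
})

test_that("single overlaps follow interval arithmetic on the same chromosome", {
  fp <- data.frame(chrom = "chr1", start = 100, end = 200, method = "HINT")
  hit <- data.frame(motif_id = "M1", chrom = "chr1", start = 150, end = 250,
                    strand = "+", p_value = 0.001, score = 10)
  cand <- intersectCatalog(fp, hit)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$start, 150)
  expect_identical(cand$end, 200)
  expect_identical(cand$motif_id, "M1")
  expect_identical(cand$strand, "+")
  expect_identical(cand$method, "HINT")

  # different chromosome: no candidate
  hit2 <- transform(hit, chrom = "chr2")
  expect_identical(nrow(intersectCatalog(fp, hit2)), 0L)

  # adjacency (zero shared bases) is not an overlap
  hit3 <- transform(hit, start = 200, end = 250)
  expect_identical(nrow(intersectCatalog(fp, hit3)), 0L)

  # strand never gates the overlap
  hit4 <- transform(hit, strand = "-")
  expect_identical(nrow(intersectCatalog(fp, hit4)), 1L)
})

test_that("the sweep matches the quadratic oracle on random instances", {
  for (seed in c(1, 2, 3)) {
    iv <- denseIntervals(200, seed = seed)
    got <- intersectCatalog(iv$footprints, iv$hits)
    want <- bruteForceIntersect(iv$footprints, iv$hits)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got$chrom, want$chrom)
    expect_identical(got$start, want$start)
    expect_identical(got$end, want$end)
    expect_identical(got$motif_id, want$motif_id)
    expect_identical(got$footprint_idx, want$footprint_idx)
    expect_identical(got$hit_idx, want$hit_idx)

    # containment: every candidate lies inside both sources
    expect_true(all(got$start >= iv$footprints$start[got$footprint_idx] &
                      got$end <= iv$footprints$end[got$footprint_idx]))
    expect_true(all(got$start >= iv$hits$start[got$hit_idx] &
                      got$end <= iv$hits$end[got$hit_idx]))
    expect_true(all(got$start < got$end))
  }
})

test_that("intersection is symmetric in the overlap coordinates", {
  iv <- denseIntervals(100, seed = 9)
  a <- intersectCatalog(iv$footprints, iv$hits)
  hitsAsFp <- data.frame(chrom = iv$hits$chrom, start = iv$hits$start,
                         end = iv$hits$end, stringsAsFactors = FALSE)
  fpAsHits <- data.frame(motif_id = sprintf("F%04d", seq_len(nrow(iv$footprints))),
                         chrom = iv$footprints$chrom,
                         start = iv$footprints$start,
                         end = iv$footprints$end, strand = ".",
                         stringsAsFactors = FALSE)
  b <- intersectCatalog(hitsAsFp, fpAsHits)
  key <- function(x) sort(paste(x$chrom, x$start, x$end))
  expect_identical(key(a), key(b))
})

test_that("a footprint tree intersects into a bagged, minted candidate set", {
  reg <- localRegistry()
  fpDir <- withr::local_tempdir()
  outDir <- withr::local_tempdir()
  tissues <- c("adrenal gland", "liver", "urinary bladder")
  generateFootprintTree(fpDir, tissues, seeds = c(16, 20),
                        methods = c("HINT", "WELLINGTON"),
                        nPerFile = 15,
                        chromSizes = c(chr1 = 2000L, chr2 = 1500L))
  hits <- denseIntervals(60, seed = 13)$hits

  res <- intersectPerBag(fpDir, hits, outDir, reg, seed = 14)
  expect_identical(nrow(res$files), 3L * 2L * 2L)
  expect_true(all(res$files$ok))
  expect_true(all(file.exists(res$files$output)))

  # per-file results equal an independent per-file intersection
  one <- res$files[res$files$tissue == "liver" &
                     res$files$method == "hint", ][1, ]
  fp <- readBed(one$input)
  fp$method <- one$method
  expect_identical(nrow(bruteForceIntersect(fp, hits)),
                   one$n_candidates)
  expect_identical(length(readLines(one$output)), one$n_candidates)

  # outputs form a valid bag of bags whose identifier resolves
  expect_length(res$inner, 3L * 2L)
  expect_true(verifyContent(reg, res$outer$record@curie, res$outer$archive))
  report <- materializeRecursive(readBag(res$outer$archive), reg,
                                 maxDepth = 2)
  expect_true(report$valid && report$complete)
  expect_length(report$children, 6L)
  expect_true(all(vapply(report$children, `[[`, TRUE, "valid")))
})

test_that("empty footprint files yield empty but present candidate files", {
  reg <- localRegistry()
  fpDir <- withr::local_tempdir()
  d <- file.path(fpDir, "liver", "seed16")
  dir.create(d, recursive = TRUE)
  writeLines(character(), file.path(d, "hint.bed"))
  res <- intersectPerBag(fpDir, denseIntervals(10, 2)$hits,
                         withr::local_tempdir(), reg, seed = 15)
  expect_true(res$files$ok)
  expect_identical(res$files$n_candidates, 0L)
})
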