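test_that("creating a bag enumerates the tree and validates complete", {
  dir <- makeTree(seed = 3, nFiles = 3)
  rel <- list.files(dir, recursive = TRUE)
  bag <- createBag(dir, info = c("External-Description" = "fixture"))

  expect_s4_class(bag, "BDBag")
  expect_setequal(payload(bag)$path, paste0("data/", rel))
  expect_true(all(c("md5", "sha256") %in% names(payload(bag))))
  expect_false(anyNA(payload(bag)$md5))
  expect_false(anyNA(payload(bag)$sha256))

  rep <- validateBag(bag, "full")
  expect_true(isValid(rep))
  expect_true(isComplete(rep))
  expect_identical(nrow(fixityErrors(rep)), 0L)
  expect_true(rep@oxumOK)
})

test_that("an empty directory yields a structurally valid empty bag", {
  dir <- withr::local_tempdir()
  bag <- createBag(dir)
  expect_identical(nrow(payload(bag)), 0L)
  expect_identical(bagInfo(bag)[["Payload-Oxum"]], "0.0")
  expect_true(validateBag(bag, "full")@structuralOK)
})

test_that("bad inputs are rejected", {
  expect_error(createBag(file.path(tempdir(), "no-such-dir")),
               class = "fairbag_input_error")
  dir <- makeTree(seed = 4, nFiles = 1)
  expect_error(createBag(dir, algorithms = "crc32"),
               class = "fairbag_configuration_error")
  bag <- createBag(dir)
  expect_error(createBag(dir), class = "fairbag_input_error") # already a bag
})

test_that("remote references make a bag holey and keep fixity checkable", {
  dir <- makeTree(seed = 5, nFiles = 2)
  bag <- createBag(dir)
  bag <- addRemoteReference(bag, "https://example.org/f1.fastq.gz",
                            "data/f1.fastq.gz",
                            digests = c(md5 = strrep("a", 32)),
                            lengthBytes = 1024)
  expect_true(isHoley(bag))
  rep <- validateBag(bag, "full")
  expect_true(rep@structuralOK)
  expect_false(isComplete(rep))
  expect_identical(missingEntries(rep), "data/f1.fastq.gz")

  # duplicate target and digest-less references are refused
  expect_error(addRemoteReference(bag, "https://example.org/other",
                                  "data/f1.fastq.gz",
                                  digests = c(md5 = strrep("b", 32))),
               class = "fairbag_conflict_error")
  expect_error(addRemoteReference(bag, "https://example.org/x",
                                  "data/x", digests = character()),
               class = "fairbag_input_error")
})

test_that("a reference-only bag is tag files only and tiny", {
  dir <- withr::local_tempdir()
  bag <- createBag(dir)
  for (i in 1:3) {
    bag <- addRemoteReference(bag, sprintf("https://example.org/f%d", i),
                              sprintf("data/f%d.fastq.gz", i),
                              digests = c(md5 = strrep("c", 32)),
                              lengthBytes = 4e9)
  }
  z <- writeBag(bag, "zip", dest = file.path(withr::local_tempdir(), "b.zip"))
  # references to 12 GB of data serialize to a few kB of tag files
  expect_lt(file.size(z), 10e3)
  lines <- readLines(file.path(bagRoot(bag), "fetch.txt"))
  expect_length(lines, 3L)
})

test_that("bags round-trip through every layout", {
  for (layout in c("directory", "zip", "tgz")) {
    dir <- makeTree(seed = 10 + nchar(layout), nFiles = 4)
    bag <- createBag(dir)
    bag <- addRemoteReference(bag, "minid:abc123", "data/extra.bin",
                              digests = c(sha256 = strrep("d", 64)),
                              lengthBytes = 11)
    loc <- if (layout == "directory") {
      writeBag(bag, layout)
      bagRoot(bag)
    } else {
      writeBag(bag, layout)
    }
    back <- readBag(loc)
    expect_identical(back@version, "1.0")
    expect_identical(back@encoding, "UTF-8")
    expect_equal(payload(back)[order(payload(back)$path), ],
                 payload(bag)[order(payload(bag)$path), ],
                 ignore_attr = TRUE)
    expect_equal(remoteRefs(back), remoteRefs(bag), ignore_attr = TRUE)
    expect_identical(bagInfo(back)[["Payload-Oxum"]],
                     bagInfo(bag)[["Payload-Oxum"]])
    rep <- validateBag(back, "full")
    expect_true(rep@structuralOK)
    expect_identical(missingEntries(rep), "data/extra.bin")
  }
})

test_that("fetch.txt dialect: unknown length and special characters round-trip", {
  dir <- withr::local_tempdir()
  bag <- createBag(dir)
  bag <- addRemoteReference(bag, "https://example.org/odd",
                            "data/odd 100%.txt",
                            digests = c(md5 = strrep("e", 32)))
  line <- readLines(file.path(bagRoot(bag), "fetch.txt"))
  expect_match(line, " - ", fixed = TRUE)        # unknown length marker
  expect_match(line, "odd 100%25.txt", fixed = TRUE)
  back <- readBag(bagRoot(bag))
  expect_identical(remoteRefs(back)$path, "data/odd 100%.txt")
  expect_true(is.na(remoteRefs(back)$length_bytes))

  # unknown remote length makes the Oxum unverifiable
  rep <- validateBag(back, "fast")
  expect_false(rep@oxumOK)
  expect_match(rep@oxumReason, "unknown length")
})

test_that("non-bags and malformed fetch lines are parse errors", {
  dir <- withr::local_tempdir()
  expect_error(readBag(dir), class = "fairbag_not_a_bag_error")
  writeLines(c("BagIt-Version: 1.0", "Tag-File-Character-Encoding: UTF-8"),
             file.path(dir, "bagit.txt"))
  expect_error(readBag(dir), class = "fairbag_not_a_bag_error") # no manifests

  dir2 <- makeTree(seed = 6, nFiles = 1)
  bag <- createBag(dir2)
  writeLines("only-two fields", file.path(bagRoot(bag), "fetch.txt"))
  err <- tryCatch(readBag(bagRoot(bag)), error = identity)
  expect_s3_class(err, "fairbag_parse_error")
  expect_match(conditionMessage(err), "line 1")
})

test_that("any single-byte payload or tag tamper is detected in full mode", {
  dir <- makeTree(seed = 7, nFiles = 3)
  bag <- createBag(dir)
  victim <- payload(bag)$path[2]
  tamperFile(file.path(bagRoot(bag), victim), offset = 3L)

  rep <- validateBag(bag, "full")
  expect_false(isValid(rep))
  fx <- fixityErrors(rep)
  expect_setequal(unique(fx$path), victim)
  expect_setequal(fx$algorithm, c("md5", "sha256"))

  # restore, then tamper a tag file instead
  tamperFile(file.path(bagRoot(bag), victim), offset = 3L)
  expect_true(isValid(validateBag(bag, "full")))
  tamperFile(file.path(bagRoot(bag), "bag-info.txt"), offset = 1L)
  rep2 <- validateBag(readBag(bagRoot(bag)), "full")
  expect_true("bag-info.txt" %in% fixityErrors(rep2)$path)
})

test_that("payload additions and deletions after bagging are reported", {
  dir <- makeTree(seed = 8, nFiles = 2)
  bag <- createBag(dir)
  writeLines("stray", file.path(bagRoot(bag), "data", "stray.txt"))
  unlink(file.path(bagRoot(bag), payload(bag)$path[1]))
  rep <- validateBag(readBag(bagRoot(bag)), "full")
  expect_identical(extraFiles(rep), "data/stray.txt")
  expect_identical(missingEntries(rep), payload(bag)$path[1])
  expect_false(isValid(rep))
})

test_that("round-trip property holds across random trees and layouts", {
  for (seed in 1:5) {
    dir <- makeTree(seed = 100 + seed, nFiles = 3 + seed %% 3)
    bag <- createBag(dir)
    layout <- c("zip", "tgz")[seed %% 2 + 1]
    back <- readBag(writeBag(bag, layout))
    rep <- validateBag(back, "full")
    expect_true(isValid(rep), info = sprintf("seed %d", seed))
    expect_true(isComplete(rep))
    # Oxum consistency: declared equals recomputed size/count over payload
    expect_true(rep@oxumOK)
  }
})
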