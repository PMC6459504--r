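# Build a holey bag whose remotes live in a local file:// store.
holeyFixture <- function(nRemotes = 3, seed = 30, env = parent.frame()) {
  store <- withr::local_tempdir(.local_envir = env)
  bagDir <- withr::local_tempdir(.local_envir = env)
  bag <- createBag(bagDir)
  files <- character(nRemotes)
  withr::with_seed(seed, {
    for (i in seq_len(nRemotes)) {
      f <- file.path(store, sprintf("r%d.bin", i))
      writeBin(as.raw(sample(0:255, 50 + i, replace = TRUE)), f)
      files[i] <- f
      bag <- addRemoteReference(bag, paste0("file://", f),
                                sprintf("data/r%d.bin", i),
                                digests = c(md5 = digest::digest(file = f, algo = "md5")),
                                lengthBytes = file.size(f))
    }
  })
  list(bag = bag, files = files, store = store)
}

test_that("fetch planning enumerates non-present entries and honors filters", {
  fx <- holeyFixture(nRemotes = 3)
  plan <- planFetch(fx$bag)
  expect_length(plan@entries, 3L)
  expect_true(all(vapply(plan@entries, `[[`, "", "status") == "planned"))

  plan1 <- planFetch(fx$bag, selector = "data/r2.*")
  expect_length(plan1@entries, 1L)
  expect_identical(plan1@entries[[1]]$path, "data/r2.bin")
})

test_that("CURIE locators resolve to the registry's ordered locations", {
  reg <- localRegistry()
  store <- withr::local_tempdir()
  f <- file.path(store, "payload.bin")
  writeBin(as.raw(1:99), f)
  rec <- mintMinid(reg, file = f, seed = 6,
                   locations = c("https://cloud.example/payload.bin",
                                 paste0("file://", f)))
  bag <- createBag(withr::local_tempdir())
  bag <- addRemoteReference(bag, rec@curie, "data/payload.bin",
                            digests = c(sha256 = rec@checksum),
                            lengthBytes = 99)
  plan <- planFetch(bag, reg)
  expect_identical(plan@entries[[1]]$candidates, rec@locations)

  # unresolvable CURIE: recorded as unavailable, not fatal
  bag2 <- createBag(withr::local_tempdir())
  bag2 <- addRemoteReference(bag2, "minid:zzzzzz", "data/x.bin",
                             digests = c(md5 = strrep("a", 32)))
  plan2 <- planFetch(bag2, reg)
  expect_identical(plan2@entries[[1]]$status, "unavailable")
  res2 <- fetchAll(bag2, plan2)
  expect_identical(res2@outcomes$status, "unavailable")
})

test_that("materializing a holey bag from a local store ends valid and complete", {
  fx <- holeyFixture(nRemotes = 3, seed = 31)
  res <- materializeBag(fx$bag)
  expect_identical(res@outcomes$status, rep("fetched-verified", 3))
  expect_true(isValid(res@report))
  expect_true(isComplete(res@report))

  # idempotence: a second run has nothing to fetch
  again <- materializeBag(readBag(bagRoot(fx$bag)))
  expect_identical(again@bytesFetched, 0)
  expect_identical(nrow(again@outcomes), 0L)
})

test_that("a tampered first location falls back to the second candidate", {
  reg <- localRegistry()
  store <- withr::local_tempdir()
  good <- file.path(store, "good.bin")
  writeBin(as.raw(1:80), good)
  bad <- file.path(store, "bad.bin")
  file.copy(good, bad)
  tamperFile(bad, 10L)
  rec <- mintMinid(reg, file = good, seed = 7,
                   locations = c(paste0("file://", bad),
                                 paste0("file://", good)))
  bag <- createBag(withr::local_tempdir())
  bag <- addRemoteReference(bag, rec@curie, "data/good.bin",
                            digests = c(sha256 = rec@checksum),
                            lengthBytes = 80)
  res <- materializeBag(bag, reg)
  expect_identical(res@outcomes$status, "fetched-verified")
  expect_identical(res@outcomes$url, paste0("file://", good))
  # the corrupt copy never reached the payload; it went to quarantine
  expect_identical(digest::digest(file = file.path(bagRoot(bag), "data/good.bin"),
                                  algo = "sha256"),
                   rec@checksum)
  expect_true(dir.exists(paste0(bagRoot(bag), ".quarantine")))
})

test_that("declared-length mismatches are never placed", {
  store <- withr::local_tempdir()
  f <- file.path(store, "f.bin")
  writeBin(as.raw(1:60), f)
  bag <- createBag(withr::local_tempdir())
  bag <- addRemoteReference(bag, paste0("file://", f), "data/f.bin",
                            digests = c(md5 = digest::digest(file = f, algo = "md5")),
                            lengthBytes = 59)  # wrong on purpose
  res <- materializeBag(bag)
  expect_identical(res@outcomes$status, "fetched-corrupt")
  expect_false(file.exists(file.path(bagRoot(bag), "data/f.bin")))
})

test_that("a bag of bags materializes recursively with per-child validation", {
  reg <- localRegistry()
  work <- withr::local_tempdir()

  curies <- character(3)
  tamperedIdx <- 2L
  for (i in 1:3) {
    inner <- createBag(makeTree(seed = 40 + i, nFiles = 2,
                                dir = file.path(work, sprintf("inner%d", i))))
    if (i == tamperedIdx) {
      tamperFile(file.path(bagRoot(inner), payload(inner)$path[1]), 1L)
    }
    arch <- writeBag(inner, "zip")
    curies[i] <- mintMinid(reg, file = arch, seed = 8,
                           locations = paste0("file://", arch),
                           extra = list(content_type = "bag+zip"))@curie
  }
  dir.create(file.path(work, "outer"))
  outer <- createBag(file.path(work, "outer"))
  for (i in 1:3) {
    outer <- addRemoteReference(outer, curies[i],
                                sprintf("data/inner%d.zip", i),
                                digests = c(sha256 = resolveMinid(reg, curies[i])@checksum))
  }

  # depth 1: archives fetched but not expanded
  shallow <- materializeRecursive(readBag(bagRoot(outer)), reg, maxDepth = 1)
  expect_true(shallow$complete)
  expect_length(shallow$children, 0L)
  expect_length(shallow$unexpanded, 3L)

  # full depth: every child expanded and validated; the tampered child is
  # reported invalid without affecting its siblings
  dir.create(file.path(work, "outer2"))
  outer2 <- createBag(file.path(work, "outer2"))
  for (i in 1:3) {
    outer2 <- addRemoteReference(outer2, curies[i],
                                 sprintf("data/inner%d.zip", i),
                                 digests = c(sha256 = resolveMinid(reg, curies[i])@checksum))
  }
  deep <- materializeRecursive(readBag(bagRoot(outer2)), reg, maxDepth = 3)
  expect_true(deep$complete)
  expect_length(deep$children, 3L)
  childValid <- vapply(deep$children, `[[`, TRUE, "valid")
  expect_identical(sum(childValid), 2L)
  expect_false(childValid[[sprintf("data/inner%d.zip", tamperedIdx)]])
})
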