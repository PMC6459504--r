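test_that("manifest parsing is strict about columns and values", {
  fx <- smallManifest()
  expect_identical(nrow(fx$rows), 14L)  # 8 + 4 + 2 replicates

  tab <- utils::read.delim(fx$tsv, check.names = FALSE,
                           colClasses = "character")

  noMd5 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab[, setdiff(names(tab), "md5sum")], noMd5,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  err <- tryCatch(parseManifest(noMd5), error = identity)
  expect_s3_class(err, "fairbag_format_error")
  expect_match(conditionMessage(err), "md5sum")

  sep <- withr::local_tempfile(fileext = ".tsv")
  tab2 <- tab
  tab2$Size[3] <- "12,345"
  utils::write.table(tab2, sep, sep = "\t", quote = FALSE, row.names = FALSE)
  err2 <- tryCatch(parseManifest(sep), error = identity)
  expect_s3_class(err2, "fairbag_format_error")
  expect_match(conditionMessage(err2), "line.* 4")  # header is line 1

  dup <- withr::local_tempfile(fileext = ".tsv")
  tab3 <- tab
  tab3$`File accession`[2] <- tab3$`File accession`[1]
  utils::write.table(tab3, dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parseManifest(dup), class = "fairbag_format_error")
})

test_that("query filters are conjunctive and order-preserving", {
  fx <- smallManifest()
  ub <- filterRows(fx$rows, tissue = "urinary bladder")
  expect_identical(length(unique(ub$biosample_id)), 1L)
  expect_identical(nrow(unique(ub[, c("biosample_id", "replicate_id")])), 2L)

  expect_identical(filterRows(fx$rows), fx$rows)          # empty predicate
  expect_identical(nrow(filterRows(fx$rows, tissue = "kidney")), 0L)
  both <- filterRows(fx$rows, tissue = c("liver", "urinary bladder"),
                     file_format = "fastq")
  expect_identical(nrow(both), 6L)
  expect_identical(both$file_accession,
                   fx$rows$file_accession[fx$rows$tissue %in%
                                            c("liver", "urinary bladder")])
})

test_that("group summaries match a brute-force pass over rows", {
  for (seed in 1:3) {
    fx <- smallManifest(seed = seed)
    s <- summarizeManifest(fx$rows)
    for (g in s$group) {
      sub <- fx$rows[fx$rows$tissue == g, ]
      expect_identical(s$n_biosamples[s$group == g],
                       length(unique(sub$biosample_id)))
      expect_identical(s$n_replicates[s$group == g],
                       nrow(unique(sub[, c("biosample_id", "replicate_id")])))
      expect_identical(s$n_files[s$group == g], nrow(sub))
      expect_identical(s$total_bytes[s$group == g], sum(sub$size_bytes))
    }
    # conservation: totals equal column sums over all rows
    tot <- summaryTotals(s)
    expect_identical(unname(tot[["n_files"]]), nrow(fx$rows))
    expect_identical(unname(tot[["total_bytes"]]), sum(fx$rows$size_bytes))
  }
  empty <- summarizeManifest(smallManifest()$rows[0, ])
  expect_identical(nrow(empty), 0L)
  expect_identical(unname(summaryTotals(empty)[["n_files"]]), 0L)
})

test_that("rows convert to a holey bag with query provenance and a minted id", {
  fx <- smallManifest()
  reg <- localRegistry()
  rows <- filterRows(fx$rows, tissue = "liver")
  query <- list(predicates = list(tissue = "liver"),
                executed_on = "2024-05-06T07:08:09Z", source = fx$tsv)
  res <- rowsToHoleyBag(rows, file.path(withr::local_tempdir(), "liver"),
                        reg, title = "liver DNase-seq", query = query,
                        seed = 9)

  expect_identical(nrow(remoteRefs(res$bag)), nrow(rows))
  expect_identical(sum(!is.na(payload(res$bag)$md5)), nrow(rows))
  expect_setequal(payload(res$bag)$path[!payload(res$bag)$present],
                  paste0("data/", rows$file_accession, ".fastq"))

  # archive resolvable and verifiable through the registry
  expect_true(verifyContent(reg, res$record@curie, res$archive))
  expect_identical(resolveMinid(reg, res$record@curie)@locations,
                   paste0("file://", res$archive))

  # the query is embedded verbatim
  qj <- jsonlite::read_json(file.path(bagRoot(res$bag), "metadata",
                                      "annotations", "query-record.json"))
  expect_identical(qj$predicates$tissue, "liver")
  expect_identical(qj$executed_on, "2024-05-06T07:08:09Z")

  # a reference bag stays small relative to the data it references
  expect_lt(file.size(res$archive), sum(rows$size_bytes))
  expect_error(rowsToHoleyBag(rows[0, ], withr::local_tempdir(), reg),
               class = "fairbag_input_error")
})

test_that("partitioning builds one bag per tissue plus a bag of bags", {
  fx <- smallManifest()
  reg <- localRegistry()
  res <- partitionAndBag(fx$rows, withr::local_tempdir(), reg, seed = 10)
  expect_length(res$inner, 3L)
  expect_setequal(names(res$inner),
                  c("adrenal gland", "liver", "urinary bladder"))
  curies <- vapply(res$inner, function(x) x$record@curie, "")
  expect_setequal(remoteRefs(res$outer$bag)$locator, unname(curies))
  expect_true(verifyContent(reg, res$outer$record@curie, res$outer$archive))

  # the bag of bags materializes back to completion: the inner reference
  # bags fetch their payload from the fixture store in turn
  report <- materializeRecursive(readBag(res$outer$archive), reg,
                                 maxDepth = 2)
  expect_true(report$complete)
  expect_length(report$children, 3L)
  expect_true(all(vapply(report$children, `[[`, TRUE, "complete")))
  expect_true(all(vapply(report$children, `[[`, TRUE, "valid")))

  single <- partitionAndBag(filterRows(fx$rows, tissue = "liver"),
                            withr::local_tempdir(), reg, seed = 11)
  expect_length(single$inner, 1L)
  expect_identical(nrow(remoteRefs(single$outer$bag)), 1L)
})

test_that("fan-out arithmetic follows the plan invariants", {
  fx <- smallManifest()   # 3 tissues, 6 biosamples
  s <- summarizeManifest(fx$rows)
  plan <- planProducts(s, seeds = c(16, 20),
                       methods = c("HINT", "WELLINGTON"))
  counts <- productCounts(plan)
  expect_identical(unname(counts[["alignment_bags"]]), 3 * 2)
  expect_identical(unname(counts[["merged_alignment_files"]]), 6 * 2)
  expect_identical(unname(counts[["footprint_files"]]), 3 * 2 * 2)

  ledger <- productLedger(plan)
  expect_identical(sum(ledger$stage == "merged_alignment"), 12L)
  expect_identical(sum(ledger$stage == "footprint"), 12L)
  # every footprint product traces back to its alignment bag
  fp <- ledger[ledger$stage == "footprint", ]
  expect_true(all(fp$input %in% ledger$product[ledger$stage == "alignment"]))

  out <- withr::local_tempfile(fileext = ".json")
  planToJSON(plan, out)
  doc <- jsonlite::read_json(out)
  expect_identical(doc$counts$footprint_files, 12L)

  expect_error(planProducts(s, seeds = numeric()),
               class = "fairbag_input_error")
})
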