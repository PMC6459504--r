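# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from stored data files.

# A random directory tree of small files, deterministic under seed.
makeTree <- function(seed = 1L, nFiles = 5L, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  withr::with_seed(seed, {
    for (i in seq_len(nFiles)) {
      sub <- sample(c("", "x", "x/y"), 1)
      d <- file.path(dir, sub)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      writeBin(as.raw(sample(0:255, sample(10:200, 1), replace = TRUE)),
               file.path(d, sprintf("f%02d.bin", i)))
    }
  })
  dir
}

localRegistry <- function(env = parent.frame()) {
  openRegistry(file.path(withr::local_tempdir(.local_envir = env), "registry.jsonl"))
}

# A small three-tissue manifest spec for fast converter tests.
smallSpec <- function(seed = 1L) {
  fixtureSpec(seed = seed,
              tissues = data.frame(
                tissue = c("adrenal gland", "liver", "urinary bladder"),
                n_biosamples = c(3L, 2L, 1L),
                n_replicates = c(8L, 4L, 2L),
                stringsAsFactors = FALSE))
}

smallManifest <- function(seed = 1L, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  fx <- generateFixtureManifest(smallSpec(seed), dir)
  fx$rows <- parseManifest(fx$tsv)
  fx
}

# Quadratic all-pairs oracle for the interval intersection: one record per
# (footprint, hit) pair with >= 1 shared base on the same sequence.
bruteForceIntersect <- function(footprints, hits) {
  out <- list()
  for (i in seq_len(nrow(footprints))) {
    for (j in seq_len(nrow(hits))) {
      if (footprints$chrom[i] != hits$chrom[j]) next
      s <- max(footprints$start[i], hits$start[j])
      e <- min(footprints$end[i], hits$end[j])
      if (s < e) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = footprints$chrom[i], start = s, end = e,
          motif_id = hits$motif_id[j], footprint_idx = i, hit_idx = j,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), motif_id = character(),
                      footprint_idx = integer(), hit_idx = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$motif_id, res$end,
            res$footprint_idx, res$hit_idx, method = "radix"), ,
      drop = FALSE]
}

# Dense random intervals on short chromosomes so overlaps actually occur.
denseIntervals <- function(n, seed) {
  generateIntervals(n, n, chromSizes = c(chr1 = 2000L, chr2 = 1500L),
                    seed = seed)
}
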