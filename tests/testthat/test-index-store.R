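test_that("Parquet index round-trips records and metadata", {
  pg <- simulate_pangenome(sim_config(pivot_length = 600, n_sequences = 2,
                                      t = 4, seed = 5))
  idx <- build_index(pg, flavor = "conservation",
                     quantiles = c(0.5, 1))
  f <- withr::local_tempfile(fileext = ".parquet")
  write_index(idx, f)
  back <- read_index(f)
  expect_identical(back$records, idx$records)
  expect_identical(back$metadata[!vapply(idx$metadata, is.null, logical(1))],
                   idx$metadata[!vapply(idx$metadata, is.null, logical(1))])
  # re-serialization is byte-identical
  f2 <- withr::local_tempfile(fileext = ".parquet")
  write_index(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("an empty record set still round-trips with metadata", {
  pivot <- genome_seq("p", c(chr = "ACGT"))
  idx <- build_index(pivot, list(), flavor = "membership")
  expect_identical(nrow(idx$records), 0L)
  f <- withr::local_tempfile(fileext = ".parquet")
  write_index(idx, f)
  back <- read_index(f)
  expect_identical(nrow(back$records), 0L)
  expect_identical(back$metadata$pivot_name, "p")
})

test_that("writer rejects unsorted records and foreign annotations", {
  pg <- simulate_pangenome(sim_config(pivot_length = 300, t = 3, seed = 2))
  idx <- build_index(pg, flavor = "membership")
  f <- withr::local_tempfile(fileext = ".parquet")
  bad <- idx
  bad$records <- bad$records[rev(seq_len(nrow(bad$records))), ]
  expect_error(write_index(bad, f), "sorted")
  bad2 <- idx
  bad2$records$annotation[1] <- 99L
  bad2$records <- bad2$records[order(match(bad2$records$chrom, "chr1"),
                                     bad2$records$start, bad2$records$end,
                                     bad2$records$annotation), ]
  rownames(bad2$records) <- NULL
  expect_error(write_index(bad2, f), "roster")
})

test_that("columnar ZSTD beats uncompressed BED text on 10k+ records", {
  pg <- simulate_pangenome(sim_config(pivot_length = 60000, t = 8,
                                      snp_rate = 0.02, indel_rate = 0.002,
                                      seed = 9))
  idx <- build_index(pg, flavor = "conservation")
  expect_gte(nrow(idx$records), 1e4)
  fp <- withr::local_tempfile(fileext = ".parquet")
  fb <- withr::local_tempfile(fileext = ".bed")
  write_index(idx, fp)
  export_bed(idx, fb)
  expect_lt(file.size(fp), file.size(fb))
})

test_that("region fetch is equivalent to a full scan for queries", {
  set.seed(61)
  pg <- simulate_pangenome(sim_config(pivot_length = 1500, t = 5,
                                      snp_rate = 0.01, indel_rate = 0.001,
                                      seed = 61))
  idx <- build_index(pg, flavor = "membership")
  expect_error(read_region(idx, "nope", 0, 10), "unknown")
  expect_error(read_region(idx, "chr1", 5, 5), "i < j")
  for (rep in 1:25) {
    i <- sample(0:1300, 1)
    j <- sample((i + 60):1500, 1)
    k <- sample(c(2L, 5L, 11L, 31L), 1)
    if (j - i < k) next
    rg <- query_region("chr1", i, j, k)
    via_region <- membership(read_region(idx, "chr1", i, j), rg,
                             idx$metadata$t_prime)
    via_scan <- membership(idx$records, rg, idx$metadata$t_prime)
    expect_identical(via_region$present, via_scan$present)
  }
  # whole-chromosome fetch returns every record of that chromosome
  all_rec <- read_region(idx, "chr1", 0, 1500 + 1)
  expect_gte(nrow(all_rec), sum(idx$records$chrom == "chr1") - 2L)
})

test_that("BED export flags the nonstandard gap/sentinel dialect", {
  # unmatchable pivot block between two matching blocks leaves a gap record
  set.seed(6)
  x <- random_dna(30)
  y <- random_dna(30)
  pivot <- genome_seq("pivot", c(chr = paste0(x, "NNNN", y)))
  other <- genome_seq("g2", c(chr = paste0(x, y)))
  idx <- build_index(pivot, list(other), flavor = "membership")
  expect_true(any(idx$records$start > idx$records$end))
  f <- withr::local_tempfile(fileext = ".bed")
  export_bed(idx, f)
  lines <- readLines(f)
  expect_true(any(grepl("nonstandard", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_identical(length(body), nrow(idx$records))
  fj <- withr::local_tempfile(fileext = ".json")
  export_metadata_json(idx, fj)
  expect_identical(jsonlite::fromJSON(fj)$pivot_name, "pivot")
})
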