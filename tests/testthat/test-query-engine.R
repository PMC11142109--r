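test_that("membership over overlap records matches the worked example", {
  rec <- mem_df_for_test("chr", c(0L, 4L, 5L), c(0L, 4L, 5L), 1L)
  r2 <- membership(rec, query_region("chr", 0, 5, 2), 1L)
  expect_identical(unname(r2$present[, 1]), c(TRUE, TRUE, TRUE, FALSE))
  r4 <- membership(rec, query_region("chr", 0, 5, 4), 1L)
  expect_identical(unname(r4$present[, 1]), c(TRUE, FALSE))
  expect_identical(r4$starts, 0:1)
})

test_that("membership via MEM containment matches the overlap path", {
  mems <- mem_df_for_test("chr", c(0L, 4L), c(4L, 5L), 1L)
  r <- membership_via_mems(mems, query_region("chr", 0, 5, 4), 1L)
  expect_identical(unname(r$present[, 1]), c(TRUE, FALSE))
  # k = 1 with full MEM coverage: everything present
  r1 <- membership_via_mems(mems, query_region("chr", 0, 5, 1), 1L)
  expect_true(all(r1$present))
  # no MEMs at all: everything absent
  none <- mem_df_for_test("chr", integer(0), integer(0), integer(0))
  r0 <- membership_via_mems(none, query_region("chr", 0, 5, 2), 1L)
  expect_false(any(r0$present))
})

test_that("conservation counts follow the worked example", {
  we <- worked_pangenome()
  idx <- build_index(we, flavor = "conservation")
  c3 <- query_conservation(idx, "chr", 0, 5, 3)
  expect_identical(c3$count_others, c(2L, 2L, 1L))
  expect_identical(c3$count, c(3L, 3L, 2L))
  c5 <- query_conservation(idx, "chr", 0, 5, 5)
  expect_identical(c5$count_others, 0L)
  expect_identical(c5$count, 1L)
  c5n <- query_conservation(idx, "chr", 0, 5, 5, include_pivot = FALSE)
  expect_identical(c5n$count, 0L)
})

test_that("conservation equals the sum of per-genome membership", {
  pg <- simulate_pangenome(sim_config(pivot_length = 900, t = 6,
                                      snp_rate = 0.015, indel_rate = 0.001,
                                      seed = 13))
  mo <- build_index(pg, flavor = "membership")
  co <- build_index(pg, flavor = "conservation")
  for (k in c(2L, 11L, 31L)) {
    mem <- query_membership(mo, "chr1", 0, 900, k)
    con <- query_conservation(co, "chr1", 0, 900, k)
    expect_identical(con$count, as.integer(rowSums(mem$present)) + 1L)
  }
})

test_that("early stopping at the first decidable order is exact", {
  pg <- simulate_pangenome(sim_config(pivot_length = 700, t = 7,
                                      snp_rate = 0.02, seed = 29))
  co <- build_index(pg, flavor = "conservation")
  k <- 21L
  rg <- query_region("chr1", 0, 700, k)
  full <- conservation(co$records, rg, co$metadata$t_prime)
  # scan ranks one at a time, stopping at the first failing track
  t_prime <- co$metadata$t_prime
  stopped <- rep(t_prime, length(full$starts))
  decided <- rep(FALSE, length(full$starts))
  for (r in seq_len(t_prime)) {
    track <- co$records[co$records$annotation == r, ]
    track$annotation <- 1L
    fails <- membership(track, rg, 1L)$present[, 1] == FALSE
    newly <- fails & !decided
    stopped[newly] <- r - 1L
    decided <- decided | fails
  }
  expect_identical(stopped + 1L, full$count)
})

test_that("absence is monotone in k within each genome", {
  pg <- simulate_pangenome(sim_config(pivot_length = 600, t = 4,
                                      snp_rate = 0.02, seed = 31))
  mo <- build_index(pg, flavor = "membership")
  prev <- NULL
  for (k in c(4L, 11L, 21L)) {
    cur <- query_membership(mo, "chr1", 0, 600, k)$present
    if (!is.null(prev)) {
      # a k-mer absent at smaller k forces absence of every extension
      n <- nrow(cur)
      expect_true(all(cur[seq_len(n), ] <= prev[seq_len(n), ]))
    }
    prev <- cur
  }
})

test_that("queries respect the region and the index k-range", {
  pg <- simulate_pangenome(sim_config(pivot_length = 400, t = 3, seed = 17))
  mo <- build_index(pg, flavor = "membership", k_max = 31)
  expect_error(query_membership(mo, "chr1", 0, 400, 32), "k_max")
  expect_error(query_membership(mo, "chr1", 390, 400, 11), "shorter than k")
  expect_error(query_membership(mo, "chr1", 0, 401, 4), "exceeds")
  expect_error(query_membership(mo, "nope", 0, 10, 2), "unknown")
  mm <- build_index(pg, flavor = "membership", store = "mem", k_min = 5)
  expect_error(query_membership(mm, "chr1", 0, 400, 4), "k_min")
  co <- build_index(pg, flavor = "conservation")
  expect_error(query_membership(co, "chr1", 0, 400, 4), "flavor")
  expect_error(query_conservation(mo, "chr1", 0, 400, 4), "flavor")
})

test_that("quantile conservation floors onto retained ranks with labels", {
  pg <- simulate_pangenome(sim_config(pivot_length = 1200, t = 8,
                                      snp_rate = 0.02, indel_rate = 0.002,
                                      seed = 41))
  co <- build_index(pg, flavor = "conservation")
  dq <- build_index(pg, flavor = "conservation",
                    quantiles = seq(0.25, 1, by = 0.25))
  retained <- dq$metadata$retained_orders
  expect_identical(retained, quantile_rows(7, seq(0.25, 1, by = 0.25)))
  for (k in c(11L, 31L)) {
    full <- query_conservation(co, "chr1", 0, 1200, k)
    quant <- query_conservation(dq, "chr1", 0, 1200, k)
    expect_s3_class(quant, "quantile_conservation_result")
    floored <- vapply(full$count_others, function(x) {
      r <- c(0L, retained)
      max(r[r <= x])
    }, integer(1))
    expect_identical(quant$order, floored)
    expect_true(all(quant$fraction >= 0 & quant$fraction <= 1))
    expect_identical(quant$label[quant$order == max(retained)][1], ">=100%")
  }
})

test_that("results serialize to TSV and BedGraph", {
  we <- worked_pangenome()
  mo <- build_index(we, flavor = "membership")
  co <- build_index(we, flavor = "conservation")
  mem <- query_membership(mo, "chr", 0, 5, 2)
  con <- query_conservation(co, "chr", 0, 5, 3)
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_query_tsv(mem, ft)
  got <- read.delim(ft)
  expect_identical(names(got), c("chrom", "start", "g2", "g3"))
  expect_identical(got$g2, c(1L, 1L, 1L, 0L))
  fb <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(con, fb)
  bg <- read.delim(fb, header = FALSE)
  expect_identical(bg$V4, c(3L, 3L, 2L))
  expect_identical(bg$V3 - bg$V2, c(1L, 1L, 1L))
})
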