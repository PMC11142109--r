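test_that("order matrix sorts columns descending and preserves multisets", {
  expect_identical(order_ms(rbind(c(1L, 3L), c(2L, 1L))),
                   rbind(c(2L, 3L), c(1L, 1L)))
  L <- rbind(c(1L, 2L, 3L, 4L, 1L), c(1L, 2L, 3L, 3L, 4L))
  O <- order_ms(L)
  expect_identical(O, rbind(c(1L, 2L, 3L, 4L, 4L), c(1L, 2L, 3L, 3L, 1L)))
  for (j in seq_len(ncol(L)))
    expect_identical(sort(O[, j]), sort(L[, j]))
  single <- matrix(c(1L, 2L, 1L), nrow = 1)
  expect_identical(order_ms(single), single)
  expect_error(order_ms(list(c(1L, 2L), c(1L))), "ragged")
})

test_that("column sorting preserves the sawtooth property", {
  set.seed(202)
  ok_sawtooth <- ok_sorted <- ok_multiset <- TRUE
  for (i in 1:300) {
    t_prime <- sample(2:8, 1)
    m <- sample(5:40, 1)
    L <- do.call(rbind, lapply(seq_len(t_prime),
                               function(.) random_sawtooth_row(m)))
    O <- order_ms(L)
    ok_sawtooth <- ok_sawtooth && all(apply(O, 1, is_sawtooth))
    for (j in seq_len(m)) {
      ok_sorted <- ok_sorted && all(diff(O[, j]) <= 0)
      ok_multiset <- ok_multiset && identical(sort(O[, j]), sort(L[, j]))
    }
  }
  expect_true(ok_sawtooth)
  expect_true(ok_sorted)
  expect_true(ok_multiset)
})

test_that("order-MEMs and order overlaps reproduce the worked example", {
  O <- rbind(c(1L, 2L, 3L, 4L, 4L), c(1L, 2L, 3L, 3L, 1L))
  om <- order_mems(O, chrom = "chr")
  o1 <- om[om$annotation == 1L, ]
  expect_identical(o1$start, c(0L, 1L))
  expect_identical(o1$end, c(4L, 5L))
  o2 <- om[om$annotation == 2L, ]
  expect_identical(o2$start, c(0L, 1L, 4L))
  expect_identical(o2$end, c(3L, 4L, 5L))
  ov <- order_overlaps(om, 5L, chrom = "chr")
  expect_identical(ov[ov$annotation == 1L, ]$start, c(0L, 1L, 5L))
  expect_identical(ov[ov$annotation == 1L, ]$end, c(0L, 4L, 5L))
  expect_identical(ov[ov$annotation == 2L, ]$start, c(0L, 1L, 4L, 5L))
  expect_identical(ov[ov$annotation == 2L, ]$end, c(0L, 3L, 4L, 5L))
  # an all-zero row yields no MEMs and an all-absent overlap track
  O0 <- rbind(c(2L, 3L, 1L, 2L, 3L), c(0L, 0L, 0L, 0L, 0L))
  om0 <- order_mems(O0, chrom = "chr")
  expect_identical(nrow(om0[om0$annotation == 2L, ]), 0L)
  ov0 <- order_overlaps(om0, 5L, ranks = 1:2, chrom = "chr")
  tr2 <- ov0[ov0$annotation == 2L, ]
  expect_identical(tr2$start, 5L)
  expect_identical(tr2$end, 0L)
})

test_that("quantile row selection uses the ceiling rule", {
  expect_identical(quantile_rows(10), 1:10)
  expect_identical(quantile_rows(4, c(0.25, 0.5, 0.75, 1)), 1:4)
  expect_identical(quantile_rows(7, c(0.5, 1)), c(4L, 7L))
  expect_error(quantile_rows(10, c(0, 0.5)), "quantiles")
  expect_error(quantile_rows(10, 1.1), "quantiles")
})

test_that("order subsampling keeps retained tracks intact", {
  rec <- mem_df_for_test("chr", c(0L, 1L, 0L, 2L), c(0L, 3L, 0L, 4L),
                         c(1L, 1L, 2L, 2L))
  only2 <- subsample_orders(rec, 2L)
  expect_identical(unique(only2$annotation), 2L)
  expect_identical(nrow(only2), 2L)
  expect_identical(subsample_orders(rec, 1:2), rec)
})

test_that("containment is monotone in order rank", {
  set.seed(77)
  pg <- simulate_pangenome(sim_config(pivot_length = 800, t = 6,
                                      snp_rate = 0.02, indel_rate = 0.002,
                                      seed = 77))
  idx <- build_index(pg, flavor = "conservation", store = "mem")
  for (k in c(4L, 11L, 21L)) {
    rg <- query_region("chr1", 0, 800, k)
    pres <- membership_via_mems(idx$records, rg,
                                idx$metadata$t_prime)$present
    # presence at rank r implies presence at every lower rank
    for (r in 2:ncol(pres))
      expect_true(all(pres[, r] <= pres[, r - 1]))
  }
})
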