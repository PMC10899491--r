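# Delta SNP-index: per-bulk index arithmetic, null confidence bounds,
# sliding windows and bound-based region calling.

test_that("snp_index and delta match the defining arithmetic", {
  expect_equal(snp_index(10, 0), 1)
  expect_equal(snp_index(7, 7), 0.5)
  expect_equal(snp_index(15, 5), 0.75)
  expect_true(is.na(snp_index(0, 0)))
  expect_equal(delta_snp_index(10, 0, 0, 10), 1)
  expect_equal(delta_snp_index(12, 12, 12, 12), 0)
  expect_equal(delta_snp_index(15, 5, 5, 15), 0.5)  # 0.75 - 0.25
})

test_that("parental attribution respects genotype orientation", {
  v <- dplyr::bind_rows(
    variant_fixture(100, low_ref = 15L, low_alt = 5L,
                    high_ref = 5L, high_alt = 15L),
    variant_fixture(200, p1_gt = "1/1", p2_gt = "0/0",
                    low_ref = 15L, low_alt = 5L,
                    high_ref = 5L, high_alt = 15L)
  )
  s <- add_snp_index(v)
  # P1 = ref at site 100: M counts are ref reads
  expect_equal(s$delta[1], 0.75 - 0.25)
  # P1 = alt at site 200: attribution flips, so delta flips
  expect_equal(s$delta[2], 0.25 - 0.75)
  expect_equal(s$depth_key, c(20, 20))
  expect_error(add_snp_index(variant_fixture(1, p1_gt = "0/1")),
               "filter_parent_consistency")
})

test_that("swapping the bulks negates deltas and mirrors regions", {
  sim <- small_sim(seed = 110, qtl = qtl_spec("chr1", 2.5e6, 1.2),
                   n = 200, h2 = 0.8)
  v <- apply_filters(sim$variants)$variants
  swapped <- dplyr::rename(v,
    low_ref = high_ref, low_alt = high_alt, low_other = high_other,
    low_gt = high_gt, high_ref = low_ref, high_alt = low_alt,
    high_other = low_other, high_gt = low_gt)
  b <- null_bounds(n_individuals = 200, pool_size = 20, seed = 111)
  s1 <- scan_snpindex(v, bounds = b, pool_size = 20, n_individuals = 200)
  s2 <- scan_snpindex(swapped, bounds = b, pool_size = 20,
                      n_individuals = 200)
  expect_equal(s2$track$fitted, -s1$track$fitted)
  expect_equal(s2$regions$start, s1$regions$start)
  expect_equal(s2$regions$direction, -s1$regions$direction)
})

test_that("null bounds behave as quantiles of a depth-limited null", {
  b_wide <- null_bounds(depths = 4, confidence = 0.99999, n_sims = 20000,
                        seed = 120)
  b_mid <- null_bounds(depths = 4, confidence = 0.9, n_sims = 20000,
                       seed = 120)
  expect_lt(b_wide$lower, b_mid$lower)
  expect_gt(b_wide$upper, b_mid$upper)
  expect_true(b_wide$lower <= 0 && b_wide$upper >= 0)
  # deeper sequencing tightens the bounds (shared seed batch, 100k sims)
  b <- null_bounds(depths = c(20, 200), n_sims = 1e5, seed = 121)
  expect_lte(b$upper[b$depth == 200], b$upper[b$depth == 20])
  expect_gte(b$lower[b$depth == 200], b$lower[b$depth == 20])
  expect_error(null_bounds(confidence = 1.2), "confidence")
  expect_error(null_bounds(pool_size = 400, n_individuals = 299),
               "pool_size")
  expect_error(null_bounds(depths = c(0, 10)), "positive")
  # determinism
  expect_equal(null_bounds(depths = 50, seed = 5),
               null_bounds(depths = 50, seed = 5))
})

test_that("bounds interpolate linearly and clamp at the grid edges", {
  b <- tibble::tibble(depth = c(10, 20), lower = c(-0.4, -0.2),
                      upper = c(0.4, 0.2))
  at <- bounds_at(b, c(10, 15, 20, 5, 100))
  expect_equal(at$upper, c(0.4, 0.3, 0.2, 0.4, 0.2))
  expect_equal(at$lower, c(-0.4, -0.3, -0.2, -0.4, -0.2))
})

test_that("window means equal direct arithmetic and skip empty windows", {
  sites <- tibble::tibble(chrom = "chr1",
                          pos = c(1e6, 1.2e6, 1.4e6),
                          delta = c(0.2, 0.4, 0.9),
                          depth_key = c(40, 50, 60))
  tr <- window_track(sites, window = 2e6, step = 1e6)
  expect_equal(tr$fitted[tr$pos == 1e6], mean(c(0.2, 0.4, 0.9)))
  const <- tibble::tibble(chrom = "chr1", pos = seq(1e5, 3e6, by = 1e5),
                          delta = 0.37, depth_key = 50)
  trc <- window_track(const)
  expect_equal(trc$fitted, rep(0.37, nrow(trc)))
  lone <- tibble::tibble(chrom = "chr1", pos = 5e6, delta = 0.5,
                         depth_key = 50)
  trl <- window_track(lone, window = 2e6, step = 1e6)
  expect_true(all(abs(trl$pos - 5e6) <= 1e6))
  expect_true(all(trl$fitted == 0.5))
})

test_that("bound-based calling is vacuous under infinite bounds", {
  sim <- small_sim(seed = 112, qtl = qtl_spec("chr1", 2.5e6, 1.5),
                   n = 200, h2 = 0.9)
  v <- apply_filters(sim$variants)$variants
  sites <- add_snp_index(v[v$kind == "SNP", ])
  tr <- window_track(sites)
  vacuous <- tibble::tibble(depth = c(1, 300), lower = -1, upper = 1)
  expect_equal(nrow(call_regions_ci(tr, vacuous)), 0)
  narrow <- tibble::tibble(depth = c(1, 300), lower = -1e-6, upper = 1e-6)
  wide_call <- call_regions_ci(tr, narrow)
  expect_gt(nrow(wide_call), 0)
  inside <- tibble::tibble(chrom = "chr1", pos = c(1e6, 2e6),
                           fitted = c(0.01, -0.01), n_sites = 5,
                           mean_depth = 50)
  b <- null_bounds(depths = 50, seed = 113)
  expect_equal(nrow(call_regions_ci(inside, b)), 0)
})

test_that("a strongly selected QTL is captured by the index regions", {
  sim <- small_sim(seed = 114, qtl = qtl_spec("chr1", 2.5e6, 1.5),
                   n = 299, h2 = 0.9)
  v <- apply_filters(sim$variants)$variants
  s <- scan_snpindex(v, pool_size = sim$pools$k, n_individuals = 299,
                     seed = 115)
  hit <- s$regions$chrom == "chr1" & s$regions$start <= 2.5e6 &
    s$regions$end > 2.5e6
  expect_true(any(hit))
})
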