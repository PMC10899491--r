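# Forward simulator: marker placement, meiosis, selfing generations,
# phenotypes, pooling and pooled sequencing.

test_that("make_parents places divergent markers on the spacing grid", {
  g <- genome_spec(c(chr1 = 1e6), marker_spacing = 1e5)
  p <- make_parents(g, seed = 1)
  expect_equal(nrow(p$markers), 10)
  expect_equal(p$markers$pos, seq(1e5, 1e6, by = 1e5))
  expect_true(all(p$markers$ref != p$markers$alt))
  p2 <- make_parents(g, seed = 1)
  expect_identical(p$markers, p2$markers)
  expect_error(make_parents(genome_spec(c(chr1 = 5e4), marker_spacing = 1e5)),
               "no markers")
})

test_that("gametes are mosaics with fair strand choice", {
  g <- genome_spec(c(chr1 = 2e6, chr2 = 2e6), marker_spacing = 5e5,
                   cM_per_Mb = 0)
  p <- make_parents(g, seed = 2)
  nm <- nrow(p$markers)
  h1 <- rep(0L, nm)
  h2 <- rep(1L, nm)
  set.seed(3)
  gam <- simulate_gamete(h1, h2, g, p$markers)
  # no recombination: each chromosome is wholly one strand
  for (ch in unique(p$markers$chrom)) {
    expect_true(length(unique(gam[p$markers$chrom == ch])) == 1)
  }
  # homozygous input is returned unchanged whatever the crossovers
  g4 <- genome_spec(c(chr1 = 2e6), marker_spacing = 1e5, cM_per_Mb = 50)
  p4 <- make_parents(g4, seed = 2)
  hom <- rep(1L, nrow(p4$markers))
  expect_identical(simulate_gamete(hom, hom, g4, p4$markers), hom)
  # allele frequency at a marker over many gametes ~ 1/2
  g1 <- genome_spec(c(chr1 = 1e5), marker_spacing = 1e5)
  p1 <- make_parents(g1, seed = 2)
  set.seed(4)
  draws <- vapply(1:10000, function(i) {
    simulate_gamete(0L, 1L, g1, p1$markers)
  }, integer(1))
  expect_lt(abs(mean(draws) - 0.5), 0.02)
})

test_that("selfing generations match Mendelian expectations", {
  g <- genome_spec(c(chr1 = 1e5), marker_spacing = 1e5)
  p <- make_parents(g, seed = 5)
  f2 <- make_population(p, cross_config(n_individuals = 10000, seed = 6,
                                        generation = "F2"))
  expect_lt(abs(mean(f2$dosage == 1) - 0.5), 0.02)
  # independent oracle: selfing transition applied twice to the F1
  self_once <- function(p) {
    c(p[1] + p[2] / 4, p[2] / 2, p[3] + p[2] / 4)
  }
  f3_expected <- self_once(self_once(c(0, 1, 0)))
  expect_equal(f3_expected, c(3 / 8, 1 / 4, 3 / 8))
  f3 <- make_population(p, cross_config(n_individuals = 10000, seed = 7))
  counts <- tabulate(f3$dosage + 1, nbins = 3)
  for (k in 1:3) {
    sd3 <- 3 * sqrt(f3_expected[k] * (1 - f3_expected[k]) / 10000)
    expect_lt(abs(counts[k] / 10000 - f3_expected[k]), sd3 + 1e-9)
  }
  expect_error(make_population(p, cross_config(n_individuals = 2))$dosage,
               NA)
  f3b <- make_population(p, cross_config(n_individuals = 10000, seed = 7))
  expect_identical(f3$dosage, f3b$dosage)
})

test_that("dosage correlation decays monotonically with distance", {
  g <- genome_spec(c(chr1 = 20e6), marker_spacing = 5e6, cM_per_Mb = 4)
  p <- make_parents(g, seed = 8)
  nm <- nrow(p$markers)
  set.seed(9)
  gams <- matrix(0L, nm, 10000)
  for (j in 1:10000) {
    gams[, j] <- simulate_gamete(rep(0L, nm), rep(1L, nm), g, p$markers)
  }
  cors <- vapply(2:nm, function(k) cor(gams[1, ], gams[k, ]), numeric(1))
  expect_true(all(diff(cors) < 0))
  expect_true(all(cors > 0))
})

test_that("additive phenotypes have the designed genetic variance", {
  g <- genome_spec(c(chr1 = 1e5), marker_spacing = 1e5)
  p <- make_parents(g, seed = 10)
  f2 <- make_population(p, cross_config(n_individuals = 10000, seed = 11,
                                        generation = "F2"))
  qtl <- qtl_spec("chr1", 1e5, effect = 1.7)
  ph <- assign_phenotypes(f2, qtl, heritability = 1, seed = 12)
  expect_equal(length(unique(ph$phenotype)), 3)  # noise-free additive F2
  # closed form: F2 additive variance = a^2 / 2
  expect_lt(abs(var(ph$genetic) - 1.7^2 / 2) / (1.7^2 / 2), 0.05)
  ph0 <- assign_phenotypes(f2, qtl_spec(character(), numeric(), numeric()),
                           heritability = 0, seed = 13)
  expect_equal(ph0$genetic, rep(0, 10000))
  expect_lt(abs(sd(ph0$phenotype) - 1), 0.05)
  expect_error(assign_phenotypes(f2, qtl_spec(character(), numeric(),
                                              numeric()),
                                 heritability = 1),
               "undefined")
  expect_error(assign_phenotypes(f2, qtl_spec("chr1", 12345, 1), 0.5),
               "coincide")
})

test_that("pool selection takes the extreme tails with stable ties", {
  pools <- select_pools(tibble::tibble(id = 1:299,
                                       phenotype = rnorm(299)), 0.10)
  expect_equal(pools$k, 30)  # round(29.9) rounds half up
  expect_length(intersect(pools$low, pools$high), 0)
  p2 <- select_pools(1:10, 0.2)
  expect_equal(p2$low, c(1L, 2L))
  expect_equal(p2$high, c(9L, 10L))
  tied <- select_pools(rep(0, 10), 0.2)
  expect_equal(tied$low, c(1L, 2L))
  expect_equal(tied$high, c(9L, 10L))
  expect_error(select_pools(1:10, 0.6), "pool_fraction")
})

test_that("pooled read sampling reflects pooled allele frequencies", {
  mk <- tibble::tibble(chrom = "chr1", pos = seq_len(10000),
                       ref = "A", alt = "G", kind = "SNP")
  fake_pop <- structure(
    list(genome = genome_spec(c(chr1 = 2e4), marker_spacing = 1),
         markers = mk,
         dosage = matrix(2L, nrow(mk), 4),  # every individual homozygous alt
         generation = "F2"),
    class = "bsa_population")
  cfg <- cross_config(n_individuals = 4, bulk_depth_mean = 50,
                      seq_error_rate = 0, seed = 20)
  pools <- list(low = 1:2, high = 3:4, k = 2)
  v <- sequence_bulks(fake_pop, pools, cfg)
  expect_true(all(v$low_ref == 0L))   # p = 1, no error: all reads alt
  expect_true(all(v$high_ref == 0L))
  fake_pop$dosage <- matrix(1L, nrow(mk), 4)  # p = 0.5 everywhere
  v2 <- sequence_bulks(fake_pop, pools, cfg, seed = 21)
  frac <- sum(v2$low_alt) / sum(v2$low_alt + v2$low_ref)
  expect_lt(abs(frac - 0.5), 0.01)
  expect_error(sequence_bulks(fake_pop, list(low = integer(), high = 1:2),
                              cfg),
               "empty pool")
})

test_that("pooling enriches the causal allele relative to unlinked markers", {
  diffs <- t(vapply(1:20, function(s) {
    sim <- small_sim(seed = 100 + s, qtl = qtl_spec("chr1", 2.5e6, 1),
                     n = 299, h2 = 0.5)
    pop <- sim$population
    p_low <- rowMeans(pop$dosage[, sim$pools$low, drop = FALSE]) / 2
    p_high <- rowMeans(pop$dosage[, sim$pools$high, drop = FALSE]) / 2
    d <- abs(p_high - p_low)
    at_qtl <- d[pop$markers$chrom == "chr1" & pop$markers$pos == 2.5e6]
    unlinked <- mean(d[pop$markers$chrom == "chr2"])
    c(qtl = at_qtl, unlinked = unlinked)
  }, numeric(2)))
  expect_gt(mean(diffs[, "qtl"]), mean(diffs[, "unlinked"]))
})

test_that("the simulated VCF is byte-identical under a fixed seed", {
  sim1 <- small_sim(seed = 30, chroms = c(chr1 = 1e6), spacing = 1e5, n = 20)
  sim2 <- small_sim(seed = 30, chroms = c(chr1 = 1e6), spacing = 1e5, n = 20)
  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  write_bulk_vcf(sim1$variants, f1)
  write_bulk_vcf(sim2$variants, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("truth table and config round trip as plain text", {
  sim <- small_sim(seed = 31, qtl = qtl_spec("chr1", 1e6, 0.8, "PH"),
                   chroms = c(chr1 = 2e6), spacing = 1e5, n = 20)
  tf <- tempfile(fileext = ".tsv")
  write_truth_table(sim, tf)
  back <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(back$pos, 1e6)
  expect_equal(back$effect, 0.8)
  yf <- tempfile(fileext = ".yaml")
  write_cross_config(sim$config, yf)
  cfg2 <- read_cross_config(yf)
  expect_equal(unclass(cfg2), unclass(sim$config))
})
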