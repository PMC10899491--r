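# Interval algebra: intersection, union, exclusion, sizes and gene
# counting, with a brute-force bitmap oracle.

test_that("region sizes come straight from half-open bounds", {
  r <- region_table("Chr1", 36420000, 37240000)
  expect_equal(r$size_mb, 0.82)
  expect_error(region_table("chr1", 10, 10), "start < end")
  expect_equal(total_size_mb(r[0, ]), 0)
})

test_that("intersection reproduces shared candidate intervals", {
  x <- region_table(c("chr1", "chr2"), c(0, 100), c(50, 200))
  expect_equal(intersect_tracks(list(x, x))[, c("chrom", "start", "end")],
               x[, c("chrom", "start", "end")])
  ph7 <- region_table("Chr7", 27310000, 29690000)
  dh7 <- region_table("Chr7", 27520000, 29690000)
  shared <- intersect_tracks(list(PH = ph7, DH = dh7))
  expect_equal(shared$start, 27520000)
  expect_equal(shared$end, 29690000)
  expect_equal(shared$size_mb, 2.17)
  expect_equal(shared$provenance, "PH&DH")
  disjoint <- intersect_tracks(list(region_table("chr1", 0, 10),
                                    region_table("chr1", 20, 30)))
  expect_equal(nrow(disjoint), 0)
  expect_error(intersect_tracks(list(ph7)), "at least two")
})

test_that("union merges overlaps and counts shared intervals once", {
  same <- region_table("chr1", 0, 10)
  expect_equal(union_regions(list(same, same))$end, 10)
  u <- union_regions(list(region_table("chr1", 0, 10),
                          region_table("chr1", 5, 20)))
  expect_equal(u$start, 0)
  expect_equal(u$end, 20)
  both <- example_region_table()
  remaining <- exclude_regions(both, drop_chroms = c("Chr2", "Chr7"))
  u2 <- union_regions(list(remaining[remaining$trait == "PH", ],
                           remaining[remaining$trait == "DH", ]))
  # the chr1 interval is present in both traits but appears once
  expect_equal(sum(u2$chrom == "Chr1"), 1)
})

test_that("exclusion drops chromosomes or subtracts intervals", {
  tbl <- example_region_table()
  ph <- tbl[tbl$trait == "PH", ]
  expect_equal(nrow(exclude_regions(ph, drop_chroms = "Chr7")), 4)
  expect_equal(nrow(exclude_regions(ph, drop_chroms = "Chr99")), 5)
  split <- exclude_regions(region_table("chr1", 0, 20),
                           drop_intervals = region_table("chr1", 5, 10))
  expect_equal(split$start, c(0, 10))
  expect_equal(split$end, c(5, 20))
})

test_that("gene counting uses one-bp overlap with per-set deduplication", {
  ann <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 100,
                        end = 200)
  r <- region_table("chr1", 150, 300)
  expect_equal(count_genes(r, ann)$gene_count, 1)
  expect_equal(count_genes(r, ann[0, ])$gene_count, 0)
  tiling <- tibble::tibble(gene_id = paste0("g", 1:10), chrom = "chr1",
                           start = seq(0, 9e5, by = 1e5),
                           end = seq(0, 9e5, by = 1e5) + 1e5)
  half <- region_table("chr1", 0, 5e5)
  # brute-force overlap oracle
  brute <- sum(tiling$start < 5e5 & tiling$end > 0)
  expect_equal(count_genes(half, tiling)$gene_count, 5)
  expect_equal(count_genes(half, tiling)$gene_count, brute)
  # a gene spanning two regions counts once per region, once in the total
  two <- region_table("chr1", c(100, 300), c(200, 400))
  span <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 150,
                         end = 350)
  expect_equal(count_genes(two, span)$gene_count, c(1, 1))
  expect_equal(count_genes_total(two, span), 1)
  # midpoint mode: midpoint 250 lies in neither region
  expect_equal(count_genes(two, span, mode = "midpoint")$gene_count,
               c(0, 0))
})

test_that("interval algebra agrees with a bitmap oracle", {
  set.seed(130)
  chroms <- c("A", "B")
  for (rep in 1:10) {
    x <- random_regions(8, chroms)
    y <- random_regions(8, chroms)
    z <- random_regions(8, chroms)
    bx <- bitmap_of(x, chroms, 1e6)
    by <- bitmap_of(y, chroms, 1e6)
    # union
    u <- union_regions(list(x, y))
    bu <- lapply(chroms, function(c) bx[[c]] | by[[c]])
    names(bu) <- chroms
    expect_equal(u[, c("chrom", "start", "end")],
                 regions_of_bitmap(bu)[, c("chrom", "start", "end")])
    # intersection
    it <- intersect_tracks(list(x, y))
    bi <- lapply(chroms, function(c) bx[[c]] & by[[c]])
    names(bi) <- chroms
    expect_equal(it[, c("chrom", "start", "end")],
                 regions_of_bitmap(bi)[, c("chrom", "start", "end")])
    # subtraction
    sub <- exclude_regions(x, drop_intervals = y)
    bs <- lapply(chroms, function(c) bx[[c]] & !by[[c]])
    names(bs) <- chroms
    expect_equal(sub[, c("chrom", "start", "end")],
                 regions_of_bitmap(bs)[, c("chrom", "start", "end")])
    # commutativity / associativity / idempotence
    expect_equal(union_regions(list(y, x)), u)
    expect_equal(intersect_tracks(list(y, x)), it,
                 ignore_attr = TRUE)
    expect_equal(intersect_tracks(list(x, x)),
                 union_regions(list(x)), ignore_attr = TRUE)
    expect_equal(union_regions(list(union_regions(list(x, y)), z)),
                 union_regions(list(x, union_regions(list(y, z)))))
    # size respects disjointness
    expect_lte(total_size_mb(u),
               total_size_mb(x) + total_size_mb(y) + 1e-12)
  }
})

test_that("BED and GFF3 round trips preserve coordinates", {
  r <- region_table(c("chr1", "chr2"), c(0, 5000), c(1000, 9000),
                    trait = "PH")
  bf <- tempfile(fileext = ".bed")
  write_bed(r, bf)
  back <- read_bed(bf)
  expect_equal(back$start, r$start)
  expect_equal(back$end, r$end)
  expect_equal(back$name, c("PH", "PH"))
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t200\t.\t+\t.\tID=gene1",
    "chr1\ttest\tmRNA\t101\t200\t.\t+\t.\tID=t1;Parent=gene1",
    "chr2\ttest\tgene\t501\t900\t.\t-\t.\tID=gene2"
  ), gff)
  genes <- read_gff_genes(gff)
  expect_equal(genes$gene_id, c("gene1", "gene2"))
  expect_equal(genes$start, c(100, 500))  # half-open, 0-based
  expect_equal(genes$end, c(200, 900))
})
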