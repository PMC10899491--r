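# Shared builders for in-code fixtures. No files on disk except temp VCFs
# written by the tests themselves.

# A variant table row with sane defaults; override any field by name.
variant_fixture <- function(pos, kind = "SNP", chrom = "chr1",
                            ref = NULL, alt = NULL, qual = 1000,
                            qd = 25, n_alt = 1L,
                            p1_gt = "0/0", p2_gt = "1/1",
                            low_gt = "0/1", high_gt = "0/1",
                            low_ref = 25L, low_alt = 25L, low_other = 0L,
                            high_ref = 25L, high_alt = 25L, high_other = 0L,
                            p1_ref = 30L, p1_alt = 0L, p1_other = 0L,
                            p2_ref = 0L, p2_alt = 30L, p2_other = 0L) {
  n <- length(pos)
  if (is.null(ref)) ref <- ifelse(rep(kind, n) == "SNP", "A", "AT")
  if (is.null(alt)) alt <- ifelse(rep(kind, n) == "SNP", "G", "A")
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    kind = rep_len(kind, n),
    indel_len = ifelse(rep_len(kind, n) == "SNP", 0L, 1L),
    qual = rep_len(qual, n), qd = rep_len(qd, n),
    n_alt = rep_len(n_alt, n),
    p1_gt = rep_len(p1_gt, n), p2_gt = rep_len(p2_gt, n),
    low_gt = rep_len(low_gt, n), high_gt = rep_len(high_gt, n),
    p1_ref = rep_len(p1_ref, n), p1_alt = rep_len(p1_alt, n),
    p1_other = rep_len(p1_other, n),
    p2_ref = rep_len(p2_ref, n), p2_alt = rep_len(p2_alt, n),
    p2_other = rep_len(p2_other, n),
    low_ref = rep_len(low_ref, n), low_alt = rep_len(low_alt, n),
    low_other = rep_len(low_other, n),
    high_ref = rep_len(high_ref, n), high_alt = rep_len(high_alt, n),
    high_other = rep_len(high_other, n)
  )
}

# Minimal hand-written VCF for reader edge cases.
write_test_vcf <- function(body_lines, path = tempfile(fileext = ".vcf"),
                           contigs = c(chr1 = 1000000L, chr2 = 1000000L)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qual by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", "LOW", "HIGH", sep = "\t")
  )
  writeLines(c(header, body_lines), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, qual = "1000", info = "QD=25.00",
                    p1 = "0/0:30,0:30", p2 = "1/1:0,30:30",
                    low = "0/1:25,25:50", high = "0/1:25,25:50") {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", info, "GT:AD:DP",
        p1, p2, low, high, sep = "\t")
}

# Small simulated experiment reused across tests.
small_sim <- function(seed = 42, qtl = NULL, n = 80, h2 = 0.8,
                      chroms = c(chr1 = 5e6, chr2 = 5e6), spacing = 1e5) {
  g <- genome_spec(chroms, marker_spacing = spacing)
  cfg <- cross_config(n_individuals = n, heritability = h2, seed = seed)
  if (is.null(qtl)) qtl <- qtl_spec(character(), numeric(), numeric())
  simulate_bsa_experiment(g, qtl, cfg)
}

# Brute-force O(n^2) tricube weighted mean, the independent fitting oracle.
fit_track_oracle <- function(positions, values, bandwidth) {
  vapply(seq_along(positions), function(i) {
    d <- abs(positions - positions[i])
    w <- ifelse(d < bandwidth, (1 - (d / bandwidth)^3)^3, 0)
    sum(w * values) / sum(w)
  }, numeric(1))
}

# Bitmap oracle for interval algebra over a toy genome: regions are marked
# per-bp on a logical vector per chromosome.
bitmap_of <- function(regions, chroms, len) {
  out <- lapply(chroms, function(ch) logical(len))
  names(out) <- chroms
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    out[[ch]][(regions$start[i] + 1):regions$end[i]] <- TRUE
  }
  out
}

regions_of_bitmap <- function(bm) {
  purrr::map_dfr(names(bm), function(ch) {
    r <- rle(bm[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    tibble::tibble(chrom = ch, start = as.numeric(starts[keep]),
                   end = as.numeric(ends[keep]))
  }) |>
    dplyr::arrange(chrom, start)
}

random_regions <- function(n, chroms = c("A", "B"), len = 1e6) {
  start <- sample.int(len - 1000, n, replace = TRUE)
  width <- sample.int(5e4, n, replace = TRUE)
  region_table(sample(chroms, n, replace = TRUE), start,
               pmin(start + width, len))
}
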