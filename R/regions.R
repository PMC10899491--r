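# Interval algebra over candidate regions. Coordinates are half-open
# [start, end) in bp throughout, so size_mb = (end - start) / 1e6 matches
# the sizes quoted from printed region bounds. GenomicRanges does the heavy
# lifting behind the tidy surface.

#' Build a region table
#'
#' @param chrom,start,end Half-open genomic intervals (`start < end`, bp).
#' @param ... Further columns recycled to length (e.g. `trait`,
#'   `gene_number`, `provenance`).
#' @return A region tibble with `size_mb` computed.
#' @export
region_table <- function(chrom, start, end, ...) {
  out <- tibble(chrom = as.character(chrom), start = as.numeric(start),
                end = as.numeric(end), ...)
  validate_regions(out)
  out$size_mb <- (out$end - out$start) / 1e6
  out
}

validate_regions <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start >= regions$end)) {
    abort("regions must satisfy start < end")
  }
  invisible(regions)
}

regions_to_gr <- function(regions) {
  validate_regions(regions)
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end)
  )
}

# give every GRanges the union of the inputs' chromosomes so set
# operations never compare disjoint seqlevel universes
harmonize_seqlevels <- function(grs) {
  lv <- unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
  lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
}

gr_to_regions <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  ) |>
    mutate(size_mb = (.data$end - .data$start) / 1e6) |>
    arrange(.data$chrom, .data$start)
}

#' Intersect region sets
#'
#' Per chromosome, the set-theoretic intersection of the unions of each
#' input set — the "shared regions" operation used to combine marker types,
#' algorithms or traits. An empty intersection is a valid result.
#'
#' @param region_sets A list of two or more region tibbles. Names, when
#'   present, are recorded in a `provenance` column.
#' @return A region tibble.
#' @examples
#' a <- region_table("chr7", 27310000, 29690000)
#' b <- region_table("chr7", 27520000, 29690000)
#' intersect_tracks(list(a, b))
#' @export
intersect_tracks <- function(region_sets) {
  if (!is.list(region_sets) || length(region_sets) < 2) {
    abort("`region_sets` must list at least two region tables")
  }
  grs <- harmonize_seqlevels(lapply(region_sets, function(r) {
    GenomicRanges::reduce(regions_to_gr(r))
  }))
  out <- gr_to_regions(Reduce(GenomicRanges::intersect, grs))
  if (!is.null(names(region_sets)) && nrow(out) > 0) {
    out$provenance <- paste(names(region_sets), collapse = "&")
  }
  out
}

#' Union of region sets
#'
#' Merges all intervals into coordinate-sorted, overlap-free regions;
#' intervals shared between inputs are counted once.
#'
#' @param region_sets A list of region tibbles (or a single tibble).
#' @return A region tibble.
#' @export
union_regions <- function(region_sets) {
  if (is.data.frame(region_sets)) region_sets <- list(region_sets)
  grs <- harmonize_seqlevels(lapply(region_sets, regions_to_gr))
  gr_to_regions(GenomicRanges::reduce(Reduce(GenomicRanges::union, grs)))
}

#' Exclude chromosomes or intervals from a region set
#'
#' Dropping whole chromosomes preserves every other column (gene counts,
#' provenance); subtracting intervals rebuilds coordinates and may split
#' regions.
#'
#' @param regions A region tibble.
#' @param drop_chroms Chromosome names to remove outright.
#' @param drop_intervals A region tibble of intervals to subtract.
#' @return A region tibble.
#' @examples
#' r <- region_table("chr1", 0, 20e6)
#' exclude_regions(r, drop_intervals = region_table("chr1", 5e6, 10e6))
#' @export
exclude_regions <- function(regions, drop_chroms = NULL,
                            drop_intervals = NULL) {
  validate_regions(regions)
  out <- regions
  if (!is.null(drop_chroms)) {
    out <- out[!out$chrom %in% drop_chroms, ]
  }
  if (!is.null(drop_intervals) && nrow(out) > 0) {
    grs <- harmonize_seqlevels(list(
      GenomicRanges::reduce(regions_to_gr(out)),
      regions_to_gr(drop_intervals)))
    gr <- GenomicRanges::setdiff(grs[[1]], grs[[2]])
    out <- gr_to_regions(gr)
  }
  out
}

#' Total size of a region set in Mb
#'
#' @param regions A region tibble (may be empty).
#' @return `sum(end - start) / 1e6` at full precision (round for reports).
#' @export
total_size_mb <- function(regions) {
  if (nrow(regions) == 0) return(0)
  validate_regions(regions)
  sum(regions$end - regions$start) / 1e6
}

#' Count annotated genes per region
#'
#' A gene is counted in a region when its interval overlaps the region
#' (`mode = "overlap"`, >= 1 bp, the default) or when its midpoint falls
#' inside (`mode = "midpoint"`). A gene spanning two regions counts once in
#' each; use [count_genes_total()] for a deduplicated total.
#'
#' @param regions A region tibble.
#' @param annotation A gene table: `gene_id`, `chrom`, `start`, `end`
#'   (half-open bp), e.g. from [read_gff_genes()].
#' @param mode `"overlap"` or `"midpoint"`.
#' @return `regions` with a `gene_count` column.
#' @export
count_genes <- function(regions, annotation,
                        mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  validate_regions(regions)
  if (nrow(annotation) == 0) {
    regions$gene_count <- 0L
    return(regions)
  }
  annotation <- arrange(annotation, .data$chrom, .data$start)
  gr_genes <- gene_query_gr(annotation, mode)
  gr_reg <- regions_to_gr(regions)
  regions$gene_count <- GenomicRanges::countOverlaps(gr_reg, gr_genes)
  regions
}

gene_query_gr <- function(annotation, mode) {
  validate_regions(annotation)
  if (mode == "midpoint") {
    mid <- floor((annotation$start + annotation$end) / 2)
    GenomicRanges::GRanges(annotation$chrom,
                           IRanges::IRanges(mid + 1, mid + 1))
  } else {
    regions_to_gr(annotation)
  }
}

#' @rdname count_genes
#' @return `count_genes_total()`: the number of distinct genes overlapping
#'   any region in the set.
#' @export
count_genes_total <- function(regions, annotation,
                              mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  if (nrow(annotation) == 0 || nrow(regions) == 0) return(0L)
  hits <- GenomicRanges::countOverlaps(gene_query_gr(annotation, mode),
                                       regions_to_gr(regions))
  sum(hits > 0)
}

#' Sum a reported gene-number column over distinct intervals
#'
#' When combining region sets that carry published per-region gene numbers,
#' intervals shared between sets must be counted once. This sums
#' `gene_number` over distinct (chrom, start, end) rows.
#'
#' @param regions A region tibble with a `gene_number` column.
#' @return The deduplicated total.
#' @export
sum_gene_numbers <- function(regions) {
  d <- distinct(regions, .data$chrom, .data$start, .data$end,
                .keep_all = TRUE)
  sum(d$gene_number)
}

#' Read and write regions as BED
#'
#' BED uses 0-based half-open coordinates, matching the package's internal
#' convention, so the round trip is exact. Extra columns beyond the first
#' three are written as BED name/score-style columns.
#'
#' @param regions A region tibble.
#' @param path File path.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` returns a
#'   region tibble.
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  name <- if ("trait" %in% names(regions)) regions$trait else "."
  readr::write_tsv(
    tibble(chrom = regions$chrom, start = format_bp(regions$start),
           end = format_bp(regions$end), name = name),
    path, col_names = FALSE
  )
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  out <- tibble(chrom = as.character(raw[[1]]), start = as.numeric(raw[[2]]),
                end = as.numeric(raw[[3]]))
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out$size_mb <- (out$end - out$start) / 1e6
  validate_regions(out)
  out
}

#' Read gene records from a GFF3 file
#'
#' Imports the annotation with rtracklayer and returns gene features as a
#' half-open gene table for [count_genes()].
#'
#' @param path A GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`).
#' @return A tibble: `gene_id`, `chrom`, `start`, `end` (half-open bp).
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- gr$ID
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

#' Example candidate-region table from a rice QTL-seq study
#'
#' Final associated regions for plant height (PH) and days to heading (DH)
#' from a published bulked-segregant study of a high-latitude japonica
#' cross, bundled as a small fixture for demonstrating the interval
#' algebra: trait, chromosome, half-open bounds and the reported per-region
#' gene numbers.
#'
#' @return A region tibble with `trait` and `gene_number` columns.
#' @examples
#' regions <- example_region_table()
#' total_size_mb(regions[regions$trait == "PH", ])
#' @export
example_region_table <- function() {
  path <- system.file("extdata", "rice_ph_dh_regions.tsv",
                      package = "bulkmapr", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  region_table(raw$chrom, raw$start, raw$end, trait = raw$trait,
               gene_number = raw$gene_number)
}
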