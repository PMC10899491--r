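# Pooled short-read sampling and VCF emission for simulated experiments.

# one sample's read draws at every marker given its true alt-allele frequency
sample_reads <- function(p_true, depth_mean, error_rate, n_sites) {
  p_obs <- p_true * (1 - error_rate) + (1 - p_true) * error_rate
  depth <- rpois(n_sites, depth_mean)
  alt <- rbinom(n_sites, depth, p_obs)
  list(ref = depth - alt, alt = alt, depth = depth)
}

call_gt <- function(ref, alt) {
  depth <- ref + alt
  frac <- ifelse(depth > 0, alt / depth, NA_real_)
  dplyr::case_when(
    depth == 0 ~ "./.",
    frac >= 0.9 ~ "1/1",
    frac <= 0.1 ~ "0/0",
    TRUE ~ "0/1"
  )
}

#' Sequence the parents and the two bulks
#'
#' Standard binomial pool-seq: at every marker the pooled alt-allele
#' frequency of each bulk is the mean dosage of its members divided by two,
#' perturbed by a symmetric per-read error; total depth is Poisson around the
#' configured mean and alt reads are Binomial(depth, frequency). Parents are
#' sequenced the same way at their (fixed) allele frequencies. QUAL and QD
#' annotations are drawn above the usual filtering thresholds, as GATK
#' emits for clean simulated sites.
#'
#' @param population A `bsa_population` from [make_population()].
#' @param pools Pool membership from [select_pools()].
#' @param config A [cross_config()].
#' @param seed Optional seed (defaults to `config$seed + 1` so the read
#'   draws are decoupled from the cross itself).
#' @return A variant tibble in the same schema as [read_bulk_vcf()] returns.
#' @export
sequence_bulks <- function(population, pools, config, seed = NULL) {
  stopifnot(inherits(population, "bsa_population"))
  if (length(pools$low) == 0 || length(pools$high) == 0) {
    abort("cannot sequence an empty pool")
  }
  set.seed(seed %||% (config$seed + 1L))
  mk <- population$markers
  n_sites <- nrow(mk)
  e <- config$seq_error_rate
  p_low <- rowMeans(population$dosage[, pools$low, drop = FALSE]) / 2
  p_high <- rowMeans(population$dosage[, pools$high, drop = FALSE]) / 2
  p1 <- sample_reads(0, config$parent_depth_mean, e, n_sites)
  p2 <- sample_reads(1, config$parent_depth_mean, e, n_sites)
  lo <- sample_reads(p_low, config$bulk_depth_mean, e, n_sites)
  hi <- sample_reads(p_high, config$bulk_depth_mean, e, n_sites)
  tibble(
    chrom = mk$chrom, pos = as.integer(mk$pos),
    ref = mk$ref, alt = mk$alt, kind = mk$kind,
    indel_len = ifelse(mk$kind == "SNP", 0L,
                       abs(nchar(mk$alt) - nchar(mk$ref))),
    qual = round(runif(n_sites, 100, 3000), 2),
    qd = round(runif(n_sites, 20, 35), 2),
    n_alt = 1L,
    p1_gt = "0/0", p2_gt = "1/1",
    low_gt = call_gt(lo$ref, lo$alt), high_gt = call_gt(hi$ref, hi$alt),
    p1_ref = p1$ref, p1_alt = p1$alt, p1_other = 0L,
    p2_ref = p2$ref, p2_alt = p2$alt, p2_other = 0L,
    low_ref = lo$ref, low_alt = lo$alt, low_other = 0L,
    high_ref = hi$ref, high_alt = hi$alt, high_other = 0L
  )
}

#' Write a four-sample VCF for a variant table
#'
#' Emits VCF 4.2 with samples P1, P2, LOW, HIGH, FORMAT `GT:AD:DP`, the QD
#' annotation in INFO and the site QUAL column. Output is deterministic:
#' identical tables give byte-identical files.
#'
#' @param variants A variant tibble ([sequence_bulks()] / [read_bulk_vcf()]
#'   schema).
#' @param path Output path.
#' @param genome Optional [genome_spec()]; when given, contig header lines
#'   carry the true chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(variants, path, genome = NULL) {
  v <- arrange(variants, .data$chrom, .data$pos)
  if (is.null(genome)) {
    contigs <- summarise(group_by(v, .data$chrom),
                         length = max(.data$pos) + 1L, .groups = "drop")
  } else {
    contigs <- tibble(chrom = genome$chromosomes$name,
                      length = as.integer(genome$chromosomes$length))
  }
  fmt_sample <- function(gt, ref, alt) {
    paste0(gt, ":", ref, ",", alt, ":", ref + alt)
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkmapr",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, contigs$length),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant Confidence/Quality by Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "P1", "P2", "LOW", "HIGH", sep = "\t")
  )
  body <- paste(
    v$chrom, as.integer(v$pos), ".", v$ref, v$alt,
    formatC(v$qual, format = "f", digits = 2), "PASS",
    paste0("QD=", formatC(v$qd, format = "f", digits = 2)), "GT:AD:DP",
    fmt_sample(v$p1_gt, v$p1_ref, v$p1_alt),
    fmt_sample(v$p2_gt, v$p2_ref, v$p2_alt),
    fmt_sample(v$low_gt, v$low_ref, v$low_alt),
    fmt_sample(v$high_gt, v$high_ref, v$high_alt),
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Simulate a complete bulk-segregant sequencing experiment
#'
#' Runs the whole generative chain — divergent inbred parents, F1, selfing to
#' the configured generation, additive phenotypes, extreme-tail pooling and
#' pooled sequencing — and returns the variant table together with the ground
#' truth (QTLs, phenotypes, pool membership).
#'
#' @param genome A [genome_spec()].
#' @param qtls A [qtl_spec()] tibble (may have zero rows for a null run).
#' @param config A [cross_config()]; `config$seed` controls everything.
#' @return An object of class `bsa_sim`: list with `variants`, `truth`
#'   (QTL table), `phenotypes`, `pools`, `population`, `config`.
#' @examples
#' g <- genome_spec(c(chr1 = 2e6), marker_spacing = 1e5)
#' sim <- simulate_bsa_experiment(g, qtl_spec("chr1", 1e6, 1), cross_config(n_individuals = 50))
#' sim$variants
#' @export
simulate_bsa_experiment <- function(genome, qtls = qtl_spec(character(), numeric(), numeric()),
                                    config = cross_config()) {
  parents <- make_parents(genome, seed = config$seed)
  pop <- make_population(parents, config)
  phen <- assign_phenotypes(pop, qtls, config$heritability,
                            seed = config$seed + 2L)
  pools <- select_pools(phen, config$pool_fraction)
  variants <- sequence_bulks(pop, pools, config, seed = config$seed + 1L)
  truth <- qtls
  phen$pool <- dplyr::case_when(phen$id %in% pools$low ~ "low",
                                phen$id %in% pools$high ~ "high",
                                TRUE ~ "none")
  structure(
    list(variants = variants, truth = truth, phenotypes = phen,
         pools = pools, population = pop, config = config, genome = genome),
    class = "bsa_sim"
  )
}

#' @export
print.bsa_sim <- function(x, ...) {
  cat("<bsa_sim> ", nrow(x$variants), " sites, ", nrow(x$truth), " QTL(s), ",
      x$config$generation, " n = ", x$config$n_individuals,
      ", pools of ", x$pools$k, "\n", sep = "")
  invisible(x)
}

#' Write the simulator's ground truth as TSV
#'
#' @param sim A `bsa_sim` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(sim, path) {
  readr::write_tsv(sim$truth, path)
  invisible(path)
}
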