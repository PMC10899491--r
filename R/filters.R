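# Staged variant filters. Each pass is independent and idempotent; the
# order used by apply_filters() is quality -> proximity -> clusters ->
# biallelic -> depth -> parent consistency, with per-pass removal counts.

#' Filter thresholds for bulk-segregant variant tables
#'
#' Defaults are the conventional QTL-seq settings: drop sites with
#' QUAL < 30 or QD < 2, SNPs within 5 bp of an InDel, InDel pairs within
#' 10 bp, runs of more than 2 variants linked by gaps of at most 5 bp, and
#' sites where either bulk has fewer than 4 reads. `seq_error_rate` sets the
#' noise floor for the parent-consistency pass: a bulk allele carried by
#' neither parent triggers removal only above twice this rate.
#'
#' @param min_qual,min_qd Quality and quality-by-depth minima (strictly-below
#'   removal).
#' @param snp_indel_dist SNP-to-InDel exclusion distance in bp.
#' @param indel_indel_dist InDel-pair exclusion distance in bp.
#' @param cluster_window,cluster_max Window (bp) and maximum run size for the
#'   variant-cluster rule.
#' @param min_bulk_depth Minimum ref+alt depth required in each bulk.
#' @param seq_error_rate Sequencing error rate used for the parent-consistency
#'   noise floor.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_qual = 30, min_qd = 2.0, snp_indel_dist = 5,
                          indel_indel_dist = 10, cluster_window = 5,
                          cluster_max = 2, min_bulk_depth = 4,
                          seq_error_rate = 0.001) {
  vals <- list(min_qual = min_qual, min_qd = min_qd,
               snp_indel_dist = snp_indel_dist,
               indel_indel_dist = indel_indel_dist,
               cluster_window = cluster_window, cluster_max = cluster_max,
               min_bulk_depth = min_bulk_depth,
               seq_error_rate = seq_error_rate)
  if (any(unlist(vals) < 0)) abort("filter thresholds must be >= 0")
  structure(vals, class = "filter_config")
}

#' Variant filters
#'
#' Six independent passes over a variant table, each returning the kept
#' rows:
#' * `filter_quality()`: keeps `qual >= min_qual` and `qd >= min_qd`
#'   (records lacking QD pass the QD test).
#' * `filter_proximity()`: removes SNPs within `snp_indel_dist` bp of any
#'   InDel, and both members of any InDel pair within `indel_indel_dist` bp
#'   (distances on the same chromosome, against the full input table).
#' * `filter_clusters()`: removes every member of any maximal run of more
#'   than `cluster_max` variants pairwise linked by gaps of at most
#'   `cluster_window` bp.
#' * `filter_biallelic()`: keeps sites with exactly one ALT allele and no
#'   third-allele reads in any sample.
#' * `filter_depth()`: keeps sites where each bulk has at least
#'   `min_bulk_depth` reads.
#' * `filter_parent_consistency()`: keeps sites where both parents are
#'   homozygous for different alleles and no bulk shows a parent-absent
#'   allele above twice `seq_error_rate`.
#'
#' @param variants A variant tibble ([read_bulk_vcf()] schema).
#' @param cfg A [filter_config()].
#' @return The filtered tibble; attribute `n_removed` records the pass's
#'   removal count.
#' @name variant_filters
NULL

with_removed <- function(kept, n_in) {
  attr(kept, "n_removed") <- n_in - nrow(kept)
  kept
}

#' @rdname variant_filters
#' @export
filter_quality <- function(variants, cfg = filter_config()) {
  keep <- variants$qual >= cfg$min_qual &
    (is.na(variants$qd) | variants$qd >= cfg$min_qd)
  keep[is.na(keep)] <- FALSE
  with_removed(variants[keep, ], nrow(variants))
}

#' @rdname variant_filters
#' @export
filter_proximity <- function(variants, cfg = filter_config()) {
  drop <- logical(nrow(variants))
  for (ch in unique(variants$chrom)) {
    ii <- which(variants$chrom == ch)
    kind <- variants$kind[ii]
    pos <- variants$pos[ii]
    ip <- sort(unique(pos[kind == "InDel"]))
    if (length(ip) == 0) next
    near <- function(p, ref_pos, d) {
      k <- findInterval(p, ref_pos)
      lo <- ifelse(k >= 1, p - ref_pos[pmax(k, 1)], Inf)
      hi <- ifelse(k < length(ref_pos), ref_pos[pmin(k + 1, length(ref_pos))] - p, Inf)
      pmin(lo, hi) <= d
    }
    is_snp <- kind == "SNP"
    drop[ii[is_snp]] <- near(pos[is_snp], ip, cfg$snp_indel_dist)
    is_indel <- kind == "InDel"
    ipos <- pos[is_indel]
    if (length(ip) >= 2) {
      gap_ok <- c(diff(ip) <= cfg$indel_indel_dist, FALSE) |
        c(FALSE, diff(ip) <= cfg$indel_indel_dist)
      bad_pos <- ip[gap_ok]
      drop[ii[is_indel]] <- drop[ii[is_indel]] | ipos %in% bad_pos
    }
    # two InDel alleles at the same position count as an adjacent pair
    dup <- ipos %in% ipos[duplicated(ipos)]
    drop[ii[is_indel]] <- drop[ii[is_indel]] | dup
  }
  with_removed(variants[!drop, ], nrow(variants))
}

#' @rdname variant_filters
#' @export
filter_clusters <- function(variants, cfg = filter_config()) {
  drop <- logical(nrow(variants))
  for (ch in unique(variants$chrom)) {
    ii <- which(variants$chrom == ch)
    ord <- order(variants$pos[ii])
    pos <- variants$pos[ii][ord]
    if (length(pos) < 2) next
    run_id <- cumsum(c(TRUE, diff(pos) > cfg$cluster_window))
    run_sizes <- table(run_id)
    bad_runs <- as.integer(names(run_sizes)[run_sizes > cfg$cluster_max])
    drop[ii[ord]] <- run_id %in% bad_runs
  }
  with_removed(variants[!drop, ], nrow(variants))
}

#' @rdname variant_filters
#' @export
filter_biallelic <- function(variants, cfg = NULL) {
  other <- variants$p1_other + variants$p2_other +
    variants$low_other + variants$high_other
  keep <- variants$n_alt == 1L & other == 0L
  with_removed(variants[keep, ], nrow(variants))
}

#' @rdname variant_filters
#' @export
filter_depth <- function(variants, cfg = filter_config()) {
  keep <- (variants$low_ref + variants$low_alt) >= cfg$min_bulk_depth &
    (variants$high_ref + variants$high_alt) >= cfg$min_bulk_depth
  with_removed(variants[keep, ], nrow(variants))
}

hom_allele <- function(gt) {
  # "0/0" -> "0", "1/1" -> "1", anything else -> NA
  dplyr::case_when(gt %in% c("0/0", "0|0") ~ "0",
                   gt %in% c("1/1", "1|1") ~ "1",
                   TRUE ~ NA_character_)
}

#' @rdname variant_filters
#' @export
filter_parent_consistency <- function(variants, cfg = filter_config()) {
  a1 <- hom_allele(variants$p1_gt)
  a2 <- hom_allele(variants$p2_gt)
  informative <- !is.na(a1) & !is.na(a2) & a1 != a2
  floor_rate <- 2 * cfg$seq_error_rate
  other_frac <- function(other, ref, alt) {
    tot <- other + ref + alt
    ifelse(tot > 0, other / tot, 0)
  }
  clean <- other_frac(variants$low_other, variants$low_ref, variants$low_alt) <= floor_rate &
    other_frac(variants$high_other, variants$high_ref, variants$high_alt) <= floor_rate
  with_removed(variants[informative & clean, ], nrow(variants))
}

#' Apply the full filter chain
#'
#' Runs quality, proximity, cluster, biallelic, depth and parent-consistency
#' passes in that order and logs how many records each removed.
#'
#' @param variants A variant tibble.
#' @param cfg A [filter_config()].
#' @return A list with `variants` (the filtered table) and `log` (tibble:
#'   stage, n_in, n_removed, n_out).
#' @examples
#' g <- genome_spec(c(chr1 = 2e6), marker_spacing = 1e5)
#' sim <- simulate_bsa_experiment(g, config = cross_config(n_individuals = 40))
#' apply_filters(sim$variants)$log
#' @export
apply_filters <- function(variants, cfg = filter_config()) {
  stages <- list(quality = filter_quality, proximity = filter_proximity,
                 clusters = filter_clusters, biallelic = filter_biallelic,
                 depth = filter_depth,
                 parent_consistency = filter_parent_consistency)
  log <- vector("list", length(stages))
  out <- variants
  for (i in seq_along(stages)) {
    n_in <- nrow(out)
    out <- stages[[i]](out, cfg)
    log[[i]] <- tibble(stage = names(stages)[i], n_in = n_in,
                       n_removed = attr(out, "n_removed"), n_out = nrow(out))
  }
  attr(out, "n_removed") <- NULL
  list(variants = out, log = bind_rows(log))
}
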