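# Design-level simulation experiments: null calibration of the two
# statistics and QTL recovery under the reference study design. Used to
# validate threshold calibration and power before trusting calls on real
# data.

#' Reference simulated study design
#'
#' The genome and cross used by the calibration and recovery experiments:
#' five 30-Mb chromosomes with parent-divergent markers every 20 kb, an F3
#' population of 299 with 10% tails pooled, bulks at 50X and parents at
#' 31X.
#'
#' @param seed Seed stored in the cross configuration.
#' @param heritability Trait heritability (default 0.48, which makes a
#'   unit-effect QTL worth 0.8 phenotypic standard deviations in an F3).
#' @return A list with `genome` and `config`.
#' @export
reference_design <- function(seed = 1L, heritability = 0.48) {
  list(
    genome = genome_spec(setNames(rep(30e6, 5), paste0("chr", 1:5)),
                         marker_spacing = 2e4),
    config = cross_config(n_individuals = 299, generation = "F3",
                          pool_fraction = 0.10, heritability = heritability,
                          bulk_depth_mean = 50, parent_depth_mean = 31,
                          seq_error_rate = 0.001, seed = seed)
  )
}

scan_both <- function(variants, config, pools_k, bounds, merge_gap) {
  list(
    ed = scan_ed(variants, marker_kind = "SNP", merge_gap = merge_gap),
    index = scan_snpindex(variants, marker_kind = "SNP",
                          generation = config$generation,
                          n_individuals = config$n_individuals,
                          pool_size = pools_k, bounds = bounds,
                          merge_gap = merge_gap)
  )
}

# each algorithm's called-region set over both marker classes (SNP and
# InDel tracks are analysed separately and their calls pooled, as in the
# standard QTL-seq workflow)
region_sets_both_kinds <- function(variants, config, pools_k, bounds,
                                   merge_gap) {
  sets <- list(ed = list(), index = list())
  for (kind in c("SNP", "InDel")) {
    if (!any(variants$kind == kind)) next
    sets$ed[[kind]] <- scan_ed(variants, marker_kind = kind,
                               merge_gap = merge_gap)$regions
    sets$index[[kind]] <- scan_snpindex(
      variants, marker_kind = kind, generation = config$generation,
      n_individuals = config$n_individuals, pool_size = pools_k,
      bounds = bounds, merge_gap = merge_gap)$regions
  }
  lapply(sets, function(s) {
    s <- s[vapply(s, nrow, integer(1)) > 0]
    if (length(s) == 0) {
      region_table(character(), numeric(), numeric())
    } else {
      union_regions(s)
    }
  })
}

#' Null calibration of both association statistics
#'
#' Simulates zero-QTL experiments under the reference design and measures,
#' per seed, the total ED-called region length as a fraction of the genome
#' and the fraction of delta SNP-index windows outside the null confidence
#' bounds. With no causal locus the ED median + 3 SD threshold should call
#' (almost) nothing, and the window exceedance should stay near the nominal
#' rate (windows are correlated, so modest excursions above 1% are
#' expected).
#'
#' @param n_seeds Number of independent simulated experiments (default 20).
#' @param base_seed Offset added to each seed index.
#' @param design A [reference_design()] list.
#' @param merge_gap Region-merge gap (default 10 kb, the calling grid).
#' @param n_sims Null-bound simulations.
#' @return A tibble with one row per seed: `ed_called_frac` (of genome
#'   length) and `index_outside_frac` (of windows).
#' @export
evaluate_null_calibration <- function(n_seeds = 20, base_seed = 1000L,
                                      design = reference_design(),
                                      merge_gap = 1e4, n_sims = 10000) {
  genome_mb <- sum(design$genome$chromosomes$length) / 1e6
  no_qtl <- qtl_spec(character(), numeric(), numeric())
  bounds <- null_bounds(n_individuals = design$config$n_individuals,
                        pool_size = round(design$config$pool_fraction *
                                            design$config$n_individuals),
                        generation = design$config$generation,
                        n_sims = n_sims, seed = base_seed)
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    cfg <- design$config
    cfg$seed <- base_seed + s
    cfg$heritability <- 0
    sim <- simulate_bsa_experiment(design$genome, no_qtl, cfg)
    fl <- apply_filters(sim$variants)$variants
    scans <- scan_both(fl, cfg, sim$pools$k, bounds, merge_gap)
    tr <- scans$index$track
    tibble(
      seed = cfg$seed,
      ed_called_frac = total_size_mb(scans$ed$regions) / genome_mb,
      index_outside_frac = mean(tr$fitted > tr$upper | tr$fitted < tr$lower)
    )
  })
}

#' QTL recovery under the reference design
#'
#' Simulates experiments with one additive QTL worth 0.8 phenotypic
#' standard deviations (heritability 0.48 for a single unit-effect F3
#' locus) in the middle of one chromosome, and records per seed and per
#' algorithm whether a called region covers the true position and how far
#' the covering region's midpoint falls from it. Each algorithm's
#' called-region set pools its SNP-track and InDel-track calls, since the
#' causal marker belongs to one class or the other.
#'
#' @inheritParams evaluate_null_calibration
#' @param qtl_chrom,qtl_pos True QTL position (defaults: chr3 at 15 Mb).
#' @param effect Additive effect in trait units (default 1).
#' @return A tibble with one row per seed and algorithm: `covered` and
#'   `midpoint_error_bp` (NA when not covered).
#' @export
evaluate_qtl_recovery <- function(n_seeds = 20, base_seed = 2000L,
                                  design = reference_design(),
                                  qtl_chrom = "chr3", qtl_pos = 15e6,
                                  effect = 1, merge_gap = 1e4,
                                  n_sims = 10000) {
  qtl <- qtl_spec(qtl_chrom, qtl_pos, effect)
  bounds <- null_bounds(n_individuals = design$config$n_individuals,
                        pool_size = round(design$config$pool_fraction *
                                            design$config$n_individuals),
                        generation = design$config$generation,
                        n_sims = n_sims, seed = base_seed)
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    cfg <- design$config
    cfg$seed <- base_seed + s
    sim <- simulate_bsa_experiment(design$genome, qtl, cfg)
    fl <- apply_filters(sim$variants)$variants
    sets <- region_sets_both_kinds(fl, cfg, sim$pools$k, bounds, merge_gap)
    purrr::map_dfr(names(sets), function(alg) {
      r <- sets[[alg]]
      hit <- r$chrom == qtl_chrom & r$start <= qtl_pos & r$end > qtl_pos
      covered <- any(hit)
      mid_err <- if (covered) {
        abs((r$start[hit][1] + r$end[hit][1]) / 2 - qtl_pos)
      } else {
        NA_real_
      }
      tibble(seed = cfg$seed, algorithm = alg, covered = covered,
             midpoint_error_bp = mid_err)
    })
  })
}
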