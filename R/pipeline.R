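# End-to-end orchestration: VCF -> filters -> (ED, delta SNP-index) x
# (SNP, InDel) -> intersection -> exclusions -> gene counts, with every
# intermediate written as plain text and a JSON run log.

#' Run the full bulk-segregant association pipeline
#'
#' Reads a four-sample VCF, applies the filter chain, runs both association
#' statistics on both marker classes, intersects the requested tracks into
#' final candidate regions, applies optional exclusions and gene counting,
#' and writes all artifacts (filtered table, per-scan tracks and BEDs,
#' final regions TSV, JSON run log) to `outdir`.
#'
#' @param vcf Path to the input VCF.
#' @param outdir Output directory (created if missing).
#' @param filter_cfg A [filter_config()].
#' @param generation,n_individuals,pool_size Study design for the null
#'   bounds of the index scans.
#' @param bandwidth,power ED scan settings.
#' @param window,step,confidence,n_sims Index scan settings.
#' @param grid,merge_gap Region-calling grid.
#' @param recipe Character subset of
#'   `c("ed_snp", "ed_indel", "index_snp", "index_indel")`: the tracks whose
#'   intersection forms the final regions.
#' @param drop_chroms Chromosomes excluded from the final regions (e.g.
#'   those explained by already-cloned genes).
#' @param annotation Optional gene table ([read_gff_genes()] schema) for
#'   per-region gene counts.
#' @param sample_roles Passed to [read_bulk_vcf()].
#' @param seed Seed for the null-bound simulations.
#' @param plots If `TRUE`, writes one track plot per scan (PDF).
#' @return A `bsa_report` list: filter log, the four scans, final regions
#'   and paths of everything written.
#' @export
run_bsa_pipeline <- function(vcf, outdir,
                             filter_cfg = filter_config(),
                             generation = c("F3", "F2"),
                             n_individuals = 299, pool_size = 30,
                             bandwidth = 2e6, power = 5,
                             window = 2e6, step = 1e4, confidence = 0.99,
                             n_sims = 10000, grid = 1e4, merge_gap = grid,
                             recipe = c("ed_snp", "ed_indel",
                                        "index_snp", "index_indel"),
                             drop_chroms = NULL, annotation = NULL,
                             sample_roles = c(p1 = "P1", p2 = "P2",
                                              low = "LOW", high = "HIGH"),
                             seed = 1L, plots = FALSE) {
  generation <- match.arg(generation)
  recipe <- match.arg(recipe, several.ok = TRUE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  variants <- stage("read_vcf", read_bulk_vcf(vcf, sample_roles))
  filt <- stage("filter", apply_filters(variants, filter_cfg))
  write_variant_table(filt$variants, file.path(outdir, "filtered.tsv"))
  kinds <- c(snp = "SNP", indel = "InDel")
  has_kind <- vapply(kinds, function(k) any(filt$variants$kind == k),
                     logical(1))
  bounds <- stage("null_bounds",
                  null_bounds(n_individuals = n_individuals,
                              pool_size = pool_size,
                              generation = generation,
                              confidence = confidence, n_sims = n_sims,
                              seed = seed))
  scans <- list()
  for (k in names(kinds)) {
    if (!has_kind[[k]]) next
    ed_name <- paste0("ed_", k)
    idx_name <- paste0("index_", k)
    scans[[ed_name]] <- stage(ed_name,
      scan_ed(filt$variants, marker_kind = kinds[[k]],
              bandwidth = bandwidth, power = power, grid = grid,
              merge_gap = merge_gap))
    scans[[idx_name]] <- stage(idx_name,
      scan_snpindex(filt$variants, marker_kind = kinds[[k]],
                    generation = generation,
                    n_individuals = n_individuals, pool_size = pool_size,
                    confidence = confidence, window = window, step = step,
                    bounds = bounds, grid = grid, merge_gap = merge_gap))
    for (nm in c(ed_name, idx_name)) {
      write_track(scans[[nm]], file.path(outdir, paste0(nm, "_track.tsv")))
      if (nrow(scans[[nm]]$regions) > 0) {
        write_bed(scans[[nm]]$regions,
                  file.path(outdir, paste0(nm, "_regions.bed")))
      }
      if (plots) {
        save_track_plot(scans[[nm]],
                        file.path(outdir, paste0(nm, "_track.pdf")))
      }
    }
  }
  used <- intersect(recipe, names(scans))
  if (length(used) == 0) abort("no recipe track could be computed")
  region_sets <- lapply(scans[used], function(s) s$regions)
  final <- if (any(vapply(region_sets, nrow, integer(1)) == 0)) {
    region_table(character(), numeric(), numeric())
  } else if (length(region_sets) == 1) {
    region_sets[[1]]
  } else {
    stage("intersect", intersect_tracks(region_sets))
  }
  if (!is.null(drop_chroms) && nrow(final) > 0) {
    final <- exclude_regions(final, drop_chroms = drop_chroms)
  }
  if (!is.null(annotation) && nrow(final) > 0) {
    final <- count_genes(final, annotation)
  }
  readr::write_tsv(final, file.path(outdir, "final_regions.tsv"))
  log <- list(
    seed = seed,
    filter_config = unclass(filter_cfg),
    filter_log = filt$log,
    design = list(generation = generation, n_individuals = n_individuals,
                  pool_size = pool_size, confidence = confidence),
    settings = list(bandwidth = bandwidth, power = power, window = window,
                    step = step, grid = grid, merge_gap = merge_gap,
                    recipe = used, drop_chroms = drop_chroms),
    thresholds = lapply(scans, function(s) s$threshold),
    n_regions = lapply(scans, function(s) nrow(s$regions))
  )
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  structure(
    list(variants = filt$variants, filter_log = filt$log, scans = scans,
         final_regions = final, outdir = outdir, log = log),
    class = "bsa_report"
  )
}

#' @export
print.bsa_report <- function(x, ...) {
  cat("<bsa_report> ", length(x$scans), " scan(s), final regions: ",
      nrow(x$final_regions), " (", round(total_size_mb(x$final_regions), 2),
      " Mb)\n  artifacts in ", x$outdir, "\n", sep = "")
  invisible(x)
}
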