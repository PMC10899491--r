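# Delta SNP-index statistic: per-bulk index from parent-attributed read
# depths, simulated null confidence bounds, sliding-window track and
# out-of-bounds region calling.

#' SNP-index of one bulk
#'
#' Fraction of reads attributed to the female parent's allele:
#' \eqn{M / (M + P)}, where M and P are the read depths carrying the female
#' and male parent alleles. Undefined (NA) when the site has no reads.
#'
#' @param M,P Non-negative read depths (vectorised).
#' @return `M / (M + P)`, `NA` where `M + P == 0`.
#' @export
snp_index <- function(M, P) {
  tot <- M + P
  ifelse(tot > 0, M / tot, NA_real_)
}

#' Delta SNP-index between the two bulks
#'
#' \eqn{\Delta = M_{aa}/(M_{aa}+P_{aa}) - M_{ab}/(M_{ab}+P_{ab})}, the
#' low-bulk index minus the high-bulk index. Values lie in \eqn{[-1, 1]};
#' loci tightly linked to the trait push \eqn{|\Delta|} towards 1 while
#' unlinked loci stay near 0.
#'
#' @param m_low,p_low Female/male-parent read depths in the low bulk.
#' @param m_high,p_high Same for the high bulk.
#' @return The delta SNP-index (vectorised), `NA` where a bulk has no reads.
#' @export
delta_snp_index <- function(m_low, p_low, m_high, p_high) {
  snp_index(m_low, p_low) - snp_index(m_high, p_high)
}

#' Attribute bulk reads to parents and compute indices
#'
#' Requires parent-consistent sites (both parents homozygous, divergent):
#' the female parent's (P1) allele defines the M depths and the male
#' parent's (P2) allele the P depths in each bulk. Sites where either bulk
#' has zero depth get `NA` indices and are skipped by downstream windows.
#'
#' @param variants A filtered variant tibble.
#' @return The tibble with added columns `m_low`, `p_low`, `m_high`,
#'   `p_high`, `index_low`, `index_high`, `delta` and `depth_key`
#'   (the smaller of the two bulk depths, used to look up null bounds).
#' @export
add_snp_index <- function(variants) {
  a1 <- hom_allele(variants$p1_gt)
  if (anyNA(a1) || anyNA(hom_allele(variants$p2_gt))) {
    abort("sites with non-homozygous parents: run filter_parent_consistency() first")
  }
  p1_is_ref <- a1 == "0"
  out <- mutate(variants,
    m_low = ifelse(p1_is_ref, .data$low_ref, .data$low_alt),
    p_low = ifelse(p1_is_ref, .data$low_alt, .data$low_ref),
    m_high = ifelse(p1_is_ref, .data$high_ref, .data$high_alt),
    p_high = ifelse(p1_is_ref, .data$high_alt, .data$high_ref),
    index_low = snp_index(.data$m_low, .data$p_low),
    index_high = snp_index(.data$m_high, .data$p_high),
    delta = .data$index_low - .data$index_high,
    depth_key = pmin(.data$m_low + .data$p_low, .data$m_high + .data$p_high)
  )
  n_skipped <- sum(is.na(out$delta))
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " zero-depth site(s) carry NA delta"))
  }
  out
}

segregation_probs <- function(generation) {
  # P(dosage = 0, 1, 2) at an unlinked marker
  switch(generation,
         F2 = c(0.25, 0.5, 0.25),
         F3 = c(3 / 8, 1 / 4, 3 / 8),
         abort("unknown generation"))
}

#' Simulated null confidence bounds for the delta SNP-index
#'
#' Monte-Carlo null with no phenotype linkage: each bulk independently pools
#' `pool_size` individuals drawn from the generation's segregation ratios
#' (3/8 : 1/4 : 3/8 for F3, 1/4 : 1/2 : 1/4 for F2); read counts at each
#' depth are Binomial(depth, pooled frequency) per bulk, and the
#' (1-confidence)/2 and 1-(1-confidence)/2 quantiles of the resulting delta
#' form the bounds. The same pooled-frequency draws are reused across the
#' depth grid so bounds shrink cleanly with depth.
#'
#' @param depths Depth grid (defaults to 4..200 in steps of 2); bounds are
#'   keyed by the smaller of the two bulk depths.
#' @param n_individuals Population size (pool_size may not exceed it).
#' @param pool_size Individuals per bulk.
#' @param generation `"F3"` or `"F2"`.
#' @param confidence Two-sided confidence level in (0, 1) (default 0.99).
#' @param n_sims Null simulations per depth (default 10,000).
#' @param seed Optional seed.
#' @return A `bsa_bounds` tibble: `depth`, `lower`, `upper`.
#' @export
null_bounds <- function(depths = seq(4, 200, by = 2), n_individuals = 299,
                        pool_size = 30, generation = c("F3", "F2"),
                        confidence = 0.99, n_sims = 10000, seed = NULL) {
  generation <- match.arg(generation)
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must be in (0, 1)")
  }
  if (pool_size > n_individuals) {
    abort("`pool_size` cannot exceed `n_individuals`")
  }
  if (any(depths <= 0)) abort("depth grid must be positive")
  if (!is.null(seed)) set.seed(seed)
  probs <- segregation_probs(generation)
  pooled_freq <- function() {
    cnt <- rmultinom(n_sims, pool_size, probs)
    (cnt[2, ] + 2 * cnt[3, ]) / (2 * pool_size)
  }
  p_low <- pooled_freq()
  p_high <- pooled_freq()
  alpha <- 1 - confidence
  qs <- purrr::map_dfr(sort(depths), function(d) {
    delta <- rbinom(n_sims, d, p_low) / d - rbinom(n_sims, d, p_high) / d
    q <- quantile(delta, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    tibble(depth = d, lower = min(q[1], 0), upper = max(q[2], 0))
  })
  structure(qs, class = c("bsa_bounds", class(qs)),
            confidence = confidence, generation = generation,
            pool_size = pool_size, n_sims = n_sims)
}

#' Interpolate null bounds at arbitrary depths
#'
#' Linear interpolation between the simulated depth-grid points; depths
#' outside the grid take the nearest grid value.
#'
#' @param bounds A [null_bounds()] table.
#' @param depth Numeric depths.
#' @return A tibble with `lower` and `upper` per input depth.
#' @export
bounds_at <- function(bounds, depth) {
  if (nrow(bounds) == 1) {
    return(tibble(lower = rep(bounds$lower, length(depth)),
                  upper = rep(bounds$upper, length(depth))))
  }
  tibble(
    lower = approx(bounds$depth, bounds$lower, xout = depth, rule = 2)$y,
    upper = approx(bounds$depth, bounds$upper, xout = depth, rule = 2)$y
  )
}

#' Sliding-window track of the delta SNP-index
#'
#' Mean delta of the sites within `window/2` bp of each step-grid center;
#' windows containing no sites are absent from the result (not zero).
#'
#' @param sites Tibble from [add_snp_index()] (needs `chrom`, `pos`,
#'   `delta`, `depth_key`).
#' @param window Window width in bp (default 2 Mb).
#' @param step Step between window centers in bp (default 10 kb).
#' @return A tibble: `chrom`, `pos` (window center), `fitted` (mean delta),
#'   `n_sites`, `mean_depth`.
#' @export
window_track <- function(sites, window = 2e6, step = 1e4) {
  sites <- sites[!is.na(sites$delta), ]
  half <- window / 2
  purrr::map_dfr(split(sites, sites$chrom), function(s) {
    s <- arrange(s, .data$pos)
    pos <- s$pos
    centers <- seq(floor(min(pos) / step) * step,
                   ceiling(max(pos) / step) * step, by = step)
    lo <- findInterval(centers - half, pos) + 1L
    hi <- findInterval(centers + half, pos)
    n <- hi - lo + 1L
    keep <- n > 0L
    cd <- c(0, cumsum(s$delta))
    cq <- c(0, cumsum(s$depth_key))
    tibble(chrom = s$chrom[1], pos = centers[keep],
           fitted = (cd[hi[keep] + 1] - cd[lo[keep]]) / n[keep],
           n_sites = n[keep],
           mean_depth = (cq[hi[keep] + 1] - cq[lo[keep]]) / n[keep])
  })
}

#' Call regions where the window track escapes the null bounds
#'
#' Windows whose mean delta lies outside the interpolated confidence bounds
#' at the window's mean depth are snapped to the calling grid and merged,
#' with the same semantics as [call_regions()]. Each region records the
#' sign of its delta (which parent's allele is enriched in the low bulk).
#'
#' @param track A [window_track()] tibble.
#' @param bounds A [null_bounds()] table.
#' @param grid,merge_gap Region-calling grid parameters (default 10 kb).
#' @return A region tibble with a `direction` column (+1 or -1).
#' @export
call_regions_ci <- function(track, bounds, grid = 1e4, merge_gap = grid) {
  b <- bounds_at(bounds, track$mean_depth)
  exceed <- track$fitted > b$upper | track$fitted < b$lower
  regions <- call_regions_core(track$chrom, track$pos, exceed,
                               grid = grid, merge_gap = merge_gap)
  if (nrow(regions) == 0) {
    regions$direction <- numeric()
    return(regions)
  }
  out_track <- track[exceed, ]
  regions$direction <- purrr::map2_dbl(
    seq_len(nrow(regions)), regions$chrom,
    function(i, ch) {
      inside <- out_track$chrom == ch &
        out_track$pos >= regions$start[i] & out_track$pos < regions$end[i]
      sign(mean(sign(out_track$fitted[inside])))
    })
  regions
}

#' Run the delta SNP-index association scan
#'
#' Computes per-site delta SNP-indices for one marker class, the 2 Mb /
#' 10 kb sliding-window track, simulated 0.99 null bounds for the study
#' design, and regions whose windows escape the bounds.
#'
#' @param variants A filtered variant tibble (parents must be homozygous
#'   and divergent at every site).
#' @param marker_kind `"SNP"` or `"InDel"`.
#' @param generation `"F3"` or `"F2"`.
#' @param n_individuals,pool_size Study design for the null simulation.
#' @param confidence Confidence level for the null bounds (default 0.99).
#' @param window,step Sliding-window parameters (defaults 2 Mb / 10 kb).
#' @param n_sims Null simulations (default 10,000).
#' @param seed Seed for the null simulation.
#' @param bounds Optional precomputed [null_bounds()] table (the null
#'   depends only on the design, so it can be shared across scans).
#' @param grid,merge_gap Region-calling grid parameters.
#' @return A `bsa_scan` object (statistic `"DELTA_INDEX"`): per-window
#'   track with interpolated bounds, the bounds table, and called regions.
#' @export
scan_snpindex <- function(variants, marker_kind = c("SNP", "InDel"),
                          generation = c("F3", "F2"), n_individuals = 299,
                          pool_size = 30, confidence = 0.99,
                          window = 2e6, step = 1e4, n_sims = 10000,
                          seed = NULL, bounds = NULL, grid = 1e4,
                          merge_gap = grid) {
  marker_kind <- match.arg(marker_kind)
  generation <- match.arg(generation)
  v <- arrange(variants[variants$kind == marker_kind, ],
               .data$chrom, .data$pos)
  if (nrow(v) == 0) abort(paste0("no ", marker_kind, " sites in the table"))
  sites <- add_snp_index(v)
  if (is.null(bounds)) {
    bounds <- null_bounds(n_individuals = n_individuals,
                          pool_size = pool_size, generation = generation,
                          confidence = confidence, n_sims = n_sims,
                          seed = seed)
  }
  track <- window_track(sites, window = window, step = step)
  track <- bind_cols(track, bounds_at(bounds, track$mean_depth))
  regions <- call_regions_ci(track, bounds, grid = grid,
                             merge_gap = merge_gap)
  structure(
    list(statistic = "DELTA_INDEX", marker_kind = marker_kind,
         sites = tibble(chrom = sites$chrom, pos = sites$pos,
                        raw = sites$delta),
         track = track, threshold = NA_real_, bounds = bounds,
         regions = regions,
         params = list(generation = generation,
                       n_individuals = n_individuals,
                       pool_size = pool_size, confidence = confidence,
                       window = window, step = step, grid = grid,
                       merge_gap = merge_gap)),
    class = "bsa_scan"
  )
}
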