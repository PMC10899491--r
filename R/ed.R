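# Euclidean-distance association statistic: per-site ED, power transform,
# distance-weighted fitted curve, genome-wide median + 3 SD threshold and
# above-threshold region calling.

#' Euclidean distance between the pools' base frequencies
#'
#' \eqn{D = \sqrt{\sum_b (N_{mut,b} - N_{wt,b})^2}} over the per-base
#' frequency vectors of the two pools. D is symmetric in its arguments, 0 at
#' loci where the pools agree and \eqn{\sqrt 2} at a fully divergent
#' biallelic site.
#'
#' @param freq_mut,freq_wt Per-base frequency vectors (same base support,
#'   each summing to 1 within 1e-9).
#' @return The scalar distance D.
#' @examples
#' ed_value(c(0.9, 0.1), c(0.4, 0.6))  # sqrt(0.5)
#' @export
ed_value <- function(freq_mut, freq_wt) {
  if (length(freq_mut) != length(freq_wt)) {
    abort("frequency vectors must have the same base support")
  }
  if (abs(sum(freq_mut) - 1) > 1e-9 || abs(sum(freq_wt) - 1) > 1e-9) {
    abort("frequency vectors must each sum to 1")
  }
  sqrt(sum((freq_mut - freq_wt)^2))
}

#' Raise ED to its association power
#'
#' The distance is raised to the fifth power (by default) before smoothing,
#' which suppresses background noise while preserving strong signals.
#'
#' @param d ED value(s).
#' @param k Exponent (default 5).
#' @return `d^k`.
#' @export
ed_power <- function(d, k = 5) {
  d^k
}

# per-site ED^k from bulk allele depths (two-base ref/alt support);
# high bulk plays the mutant pool, low bulk the wild type — ED is
# symmetric so the labeling does not affect calls
ed_sites <- function(variants, power = 5) {
  f_low <- variants$low_alt / (variants$low_ref + variants$low_alt)
  f_high <- variants$high_alt / (variants$high_ref + variants$high_alt)
  d <- sqrt(2 * (f_high - f_low)^2)
  tibble(chrom = variants$chrom, pos = variants$pos,
         raw = ed_power(d, power))
}

#' Distance-weighted local fit of a genome track
#'
#' Smooths per-site statistics over physical distance with a tricube kernel:
#' \eqn{fitted_i = \sum_j w_{ij} v_j / \sum_j w_{ij}} with
#' \eqn{w_{ij} = (1 - (d_{ij}/h)^3)^3} for \eqn{d_{ij} < h}, 0 beyond, where
#' \eqn{d_{ij}} is the bp distance between sites. Sites beyond the bandwidth
#' contribute nothing, and constant input is returned unchanged.
#'
#' @param positions Ascending bp positions on one chromosome.
#' @param values Statistic values, same length.
#' @param bandwidth Kernel bandwidth in bp (default 2 Mb).
#' @return Fitted values, same length as `values`.
#' @export
fit_track <- function(positions, values, bandwidth = 2e6) {
  n <- length(positions)
  if (n != length(values)) abort("positions and values differ in length")
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("positions must be strictly increasing")
  }
  if (n == 1) {
    warn("single-site chromosome: fitted value equals the raw value")
    return(values)
  }
  lo <- findInterval(positions - bandwidth, positions) + 1L
  hi <- findInterval(positions + bandwidth, positions)
  vapply(seq_len(n), function(i) {
    jj <- lo[i]:hi[i]
    d <- abs(positions[jj] - positions[i])
    w <- (1 - (d / bandwidth)^3)^3
    w[d >= bandwidth] <- 0
    sum(w * values[jj]) / sum(w)
  }, numeric(1))
}

#' Genome-wide association threshold for fitted ED values
#'
#' `median(fitted) + 3 * sd(fitted)`, with the sample (n-1) standard
#' deviation, pooled over all chromosomes of one marker class.
#'
#' @param fitted Fitted statistic values genome-wide (length >= 2).
#' @return The scalar threshold.
#' @export
ed_threshold <- function(fitted) {
  if (length(fitted) < 2) abort("need at least 2 fitted values")
  median(fitted) + 3 * sd(fitted)
}

# shared region-calling core: snap exceeding positions to grid bins and
# merge bins separated by at most merge_gap
call_regions_core <- function(chrom, pos, exceed, grid = 1e4,
                              merge_gap = grid) {
  keep <- which(exceed)
  if (length(keep) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  size_mb = numeric()))
  }
  bins <- distinct(tibble(chrom = chrom[keep],
                          start = floor(pos[keep] / grid) * grid))
  bins <- arrange(bins, .data$chrom, .data$start)
  bins <- mutate(group_by(bins, .data$chrom),
                 new_run = c(TRUE, diff(.data$start) - grid > merge_gap),
                 run = cumsum(.data$new_run))
  out <- summarise(group_by(bins, .data$chrom, .data$run),
                   run_start = min(.data$start),
                   run_end = max(.data$start) + grid,
                   .groups = "drop")
  out <- rename(out, start = "run_start", end = "run_end")
  out <- arrange(out, .data$chrom, .data$start)
  tibble(chrom = out$chrom, start = out$start, end = out$end,
         size_mb = (out$end - out$start) / 1e6)
}

#' Call candidate regions from a fitted track
#'
#' Sites whose fitted statistic strictly exceeds the threshold are snapped
#' to 10-kb bins (`floor(pos/grid) * grid`); bins separated by at most
#' `merge_gap` are merged. Regions are half-open `[start, end)` so that
#' `size_mb = (end - start) / 1e6`.
#'
#' @param track Tibble with columns `chrom`, `pos`, `fitted`.
#' @param threshold Scalar association threshold.
#' @param grid Bin width in bp (default 10 kb).
#' @param merge_gap Maximum gap (bp) between merged bins (default `grid`).
#' @return A region tibble (`chrom`, `start`, `end`, `size_mb`); empty when
#'   nothing exceeds the threshold.
#' @export
call_regions <- function(track, threshold, grid = 1e4, merge_gap = grid) {
  call_regions_core(track$chrom, track$pos, track$fitted > threshold,
                    grid = grid, merge_gap = merge_gap)
}

#' Run the ED association scan
#'
#' Computes per-site ED^power from bulk allele depths for one marker class,
#' fits the track per chromosome, derives the genome-wide median + 3 SD
#' threshold and calls above-threshold regions.
#'
#' @param variants A filtered variant tibble.
#' @param marker_kind `"SNP"` or `"InDel"`.
#' @param bandwidth Fitting bandwidth in bp (default 2 Mb).
#' @param power ED exponent (default 5).
#' @param grid,merge_gap Region-calling grid parameters (default 10 kb).
#' @return A `bsa_scan` object: per-site track with `raw` and `fitted`, the
#'   threshold, and called regions. Use [tidy()], [glance()] and
#'   [autoplot()] on it.
#' @examples
#' g <- genome_spec(c(chr1 = 2e6), marker_spacing = 5e4)
#' sim <- simulate_bsa_experiment(g, qtl_spec("chr1", 1e6, 1),
#'                                cross_config(n_individuals = 100))
#' scan <- scan_ed(apply_filters(sim$variants)$variants)
#' glance(scan)
#' @export
scan_ed <- function(variants, marker_kind = c("SNP", "InDel"),
                    bandwidth = 2e6, power = 5, grid = 1e4,
                    merge_gap = grid) {
  marker_kind <- match.arg(marker_kind)
  v <- arrange(variants[variants$kind == marker_kind, ],
               .data$chrom, .data$pos)
  if (nrow(v) == 0) abort(paste0("no ", marker_kind, " sites in the table"))
  sites <- ed_sites(v, power = power)
  ok <- is.finite(sites$raw)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    inform(paste0(n_skipped, " zero-depth site(s) skipped"))
  }
  sites <- sites[ok, ]
  track <- mutate(group_by(sites, .data$chrom),
                  fitted = fit_track(.data$pos, .data$raw, bandwidth))
  track <- ungroup(track)
  threshold <- ed_threshold(track$fitted)
  regions <- call_regions(track, threshold, grid = grid,
                          merge_gap = merge_gap)
  structure(
    list(statistic = "ED5", marker_kind = marker_kind,
         sites = sites, track = track, threshold = threshold,
         bounds = NULL, regions = regions,
         params = list(bandwidth = bandwidth, power = power, grid = grid,
                       merge_gap = merge_gap, n_skipped = n_skipped)),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("<bsa_scan> ", x$statistic, " on ", x$marker_kind, " sites (n = ",
      nrow(x$track), ")\n", sep = "")
  if (!is.null(x$threshold) && !is.na(x$threshold)) {
    cat("  threshold (median + 3 SD): ", signif(x$threshold, 4), "\n",
        sep = "")
  } else {
    cat("  null bounds at confidence ",
        attr(x$bounds, "confidence") %||% NA, "\n", sep = "")
  }
  cat("  regions called: ", nrow(x$regions), " (",
      round(sum(x$regions$size_mb), 2), " Mb)\n", sep = "")
  invisible(x)
}
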