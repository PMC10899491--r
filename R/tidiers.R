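# broom-style accessors for scan objects.

#' Tidy a bsa_scan
#'
#' Returns the fitted track as a tibble with an `exceed` flag marking
#' entries beyond the threshold (ED scans) or outside the null bounds
#' (delta SNP-index scans).
#'
#' @param x A `bsa_scan` from [scan_ed()] or [scan_snpindex()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bsa_scan
#' @export
tidy.bsa_scan <- function(x, ...) {
  tr <- x$track
  if (x$statistic == "ED5") {
    tr$exceed <- tr$fitted > x$threshold
  } else {
    tr$exceed <- tr$fitted > tr$upper | tr$fitted < tr$lower
  }
  tr
}

#' Glance at a bsa_scan
#'
#' @param x A `bsa_scan`.
#' @param ... Unused.
#' @return A one-row tibble: statistic, marker kind, numbers of sites and
#'   regions, threshold (NA for bound-based scans) and total called Mb.
#' @method glance bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    marker_kind = x$marker_kind,
    n_sites = nrow(x$sites),
    threshold = x$threshold,
    n_regions = nrow(x$regions),
    total_mb = if (nrow(x$regions)) sum(x$regions$size_mb) else 0
  )
}

#' Export a scan's fitted track as TSV
#'
#' @param scan A `bsa_scan`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_track <- function(scan, path) {
  readr::write_tsv(tidy(scan), path)
  invisible(path)
}
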