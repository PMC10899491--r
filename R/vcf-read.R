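# Reading four-sample VCFs into the pipeline's variant-record model.

parse_ad_entry <- function(ad, j) {
  # ad: character "ref,alt1[,alt2...]"; j: 1-based alt index
  if (is.na(ad) || ad == "." || ad == "") {
    return(c(0L, 0L, 0L))
  }
  parts <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
  parts[is.na(parts)] <- 0L
  ref <- parts[1]
  alt <- if (length(parts) >= j + 1) parts[j + 1] else 0L
  other <- sum(parts) - ref - alt
  c(ref, alt, other)
}

classify_allele <- function(ref, alt, max_indel = 50L) {
  lr <- nchar(ref)
  la <- nchar(alt)
  len <- abs(la - lr)
  if (lr == 1 && la == 1) {
    list(kind = "SNP", len = 0L)
  } else if (len >= 1 && len <= max_indel) {
    list(kind = "InDel", len = len)
  } else {
    # large InDels (>50 bp) and same-length multi-base substitutions:
    # retained but outside the SNP/InDel marker classes
    list(kind = "Other", len = len)
  }
}

#' Read a four-sample bulk-segregant VCF
#'
#' Parses a VCF holding the two parents and the low/high phenotypic bulks
#' into a tidy variant table, one row per ALT allele. Multi-allelic rows are
#' kept (flagged via `n_alt`) so that downstream filters can account for
#' their removal explicitly. Allele classes follow the small-InDel
#' convention: alleles whose length difference exceeds 50 bp are retained
#' but classed `"Other"`, outside both the SNP and InDel marker classes.
#' A missing QD annotation is recorded as `NA`, never as zero.
#'
#' @param path Path to a VCF 4.x file (plain or bgzip).
#' @param sample_roles Named character vector mapping the roles `p1`, `p2`,
#'   `low`, `high` to sample names in the VCF.
#' @return A tibble with one row per (site, ALT allele): coordinates,
#'   alleles, `kind` (SNP/InDel/Other), `qual`, `qd`, `n_alt`, per-sample
#'   genotypes and (ref, alt, other) read depths.
#' @export
read_bulk_vcf <- function(path,
                          sample_roles = c(p1 = "P1", p2 = "P2",
                                           low = "LOW", high = "HIGH")) {
  need <- c("p1", "p2", "low", "high")
  if (!all(need %in% names(sample_roles))) {
    abort("`sample_roles` must name p1, p2, low and high")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  missing_roles <- sample_roles[!sample_roles %in% samples]
  if (length(missing_roles) > 0) {
    abort(paste0("sample(s) not present in VCF: ",
                 paste(missing_roles, collapse = ", ")))
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  # sortedness: no chromosome block may recur, positions nondecreasing within
  blocks <- rle(chrom)$values
  if (anyDuplicated(blocks)) {
    bad <- blocks[duplicated(blocks)][1]
    first <- which(chrom == bad & c(TRUE, chrom[-1] != chrom[-length(chrom)]))[2]
    abort(paste0("VCF is not sorted: chromosome ", bad,
                 " recurs at record ", chrom[first], ":", pos[first]))
  }
  off <- which(c(FALSE, diff(pos) < 0) & chrom == dplyr::lag(chrom))
  if (length(off) > 0) {
    abort(paste0("VCF is not sorted: record ", chrom[off[1]], ":",
                 pos[off[1]], " is out of order"))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "QD")))
  gt <- vcfR::extract.gt(vcf, "GT")
  ad <- vcfR::extract.gt(vcf, "AD")
  role_col <- function(role) match(sample_roles[[role]], samples)
  cols <- vapply(need, role_col, integer(1))
  alt_list <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]),
                       ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- alt_list[[i]]
    purrr::map_dfr(seq_along(alts), function(j) {
      cls <- classify_allele(fix[i, "REF"], alts[j])
      ads <- lapply(cols, function(ci) parse_ad_entry(ad[i, ci], j))
      tibble(
        chrom = unname(chrom[i]), pos = unname(pos[i]),
        ref = unname(fix[i, "REF"]), alt = unname(alts[j]),
        kind = unname(cls$kind), indel_len = unname(cls$len),
        qual = qual[i], qd = qd[i], n_alt = n_alt[i],
        p1_gt = unname(gt[i, cols[["p1"]]]),
        p2_gt = unname(gt[i, cols[["p2"]]]),
        low_gt = unname(gt[i, cols[["low"]]]),
        high_gt = unname(gt[i, cols[["high"]]]),
        p1_ref = ads[["p1"]][1], p1_alt = ads[["p1"]][2], p1_other = ads[["p1"]][3],
        p2_ref = ads[["p2"]][1], p2_alt = ads[["p2"]][2], p2_other = ads[["p2"]][3],
        low_ref = ads[["low"]][1], low_alt = ads[["low"]][2], low_other = ads[["low"]][3],
        high_ref = ads[["high"]][1], high_alt = ads[["high"]][2], high_other = ads[["high"]][3]
      )
    })
  })
  rows$p1_gt[is.na(rows$p1_gt)] <- "./."
  rows$p2_gt[is.na(rows$p2_gt)] <- "./."
  rows$low_gt[is.na(rows$low_gt)] <- "./."
  rows$high_gt[is.na(rows$high_gt)] <- "./."
  if (anyDuplicated(rows[c("chrom", "pos", "ref", "alt")])) {
    abort("duplicate (chrom, pos, ref, alt) records in VCF")
  }
  attr(rows, "source_file") <- path
  rows
}

#' Write / read a variant table as TSV
#'
#' Plain-text round trip of the tidy variant record model, so filtered
#' tables compose with external tools.
#'
#' @param variants A variant tibble.
#' @param path File path.
#' @return `write_variant_table()` returns `path` invisibly;
#'   `read_variant_table()` returns the tibble.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(variants, path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    ref = readr::col_character(),
                    alt = readr::col_character(),
                    kind = readr::col_character(),
                    p1_gt = readr::col_character(),
                    p2_gt = readr::col_character(),
                    low_gt = readr::col_character(),
                    high_gt = readr::col_character()
                  ))
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

gt_is_het <- function(gt) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    length(a) == 2 && !any(a == ".") && a[1] != a[2]
  }, logical(1))
}

gt_is_called <- function(gt) {
  !is.na(gt) & gt != "./." & gt != ".|." & gt != "."
}

gt_has_alt <- function(gt) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) any(a != "." & a != "0"), logical(1))
}

#' Summarise variant-table quality
#'
#' Reports the diagnostics commonly quoted for resequencing panels:
#' per-sample SNP and InDel counts (sites where the sample carries a
#' non-reference allele), the transition/transversion ratio over SNPs
#' (transitions are A<->G and C<->T), and the per-sample heterozygosity
#' ratio (heterozygous calls over called genotypes). Ts/Tv is `NA` when no
#' transversions are present.
#'
#' @param variants A variant tibble.
#' @return A list with `per_sample` (tibble: sample, n_snp, n_indel,
#'   het_ratio), `ts_tv`, `n_snp`, `n_indel`.
#' @export
qc_summary <- function(variants) {
  if (nrow(variants) == 0) abort("empty variant table")
  snps <- variants[variants$kind == "SNP", ]
  indels <- variants[variants$kind == "InDel", ]
  ts <- sum(is_transition(snps$ref, snps$alt))
  tv <- nrow(snps) - ts
  samples <- c(p1 = "p1_gt", p2 = "p2_gt", low = "low_gt", high = "high_gt")
  per_sample <- purrr::map_dfr(names(samples), function(s) {
    gcol <- variants[[samples[[s]]]]
    called <- gt_is_called(gcol)
    tibble(
      sample = s,
      n_snp = sum(variants$kind == "SNP" & called & gt_has_alt(gcol)),
      n_indel = sum(variants$kind == "InDel" & called & gt_has_alt(gcol)),
      het_ratio = if (any(called)) sum(gt_is_het(gcol[called])) / sum(called)
                  else NA_real_
    )
  })
  list(per_sample = per_sample,
       ts_tv = if (tv == 0) NA_real_ else ts / tv,
       n_snp = nrow(snps), n_indel = nrow(indels))
}
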