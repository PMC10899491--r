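#' Define a genome for forward simulation
#'
#' A genome specification holds the chromosome lengths, the spacing of
#' parent-divergent markers, and a uniform recombination rate. It stands in
#' for a reference assembly when simulating a biparental cross: every marker
#' is a site where the two inbred parents carry different alleles.
#'
#' @param chromosomes Chromosome lengths in bp: either a named numeric vector
#'   (`c(chr1 = 30e6, ...)`) or a data frame with columns `name` and `length`.
#' @param marker_spacing Distance in bp between consecutive parent-divergent
#'   markers (default 20 kb, roughly the density left after stringent
#'   filtering of a japonica x japonica cross).
#' @param cM_per_Mb Uniform genetic map rate in centimorgan per megabase
#'   (default 4, rice-typical).
#' @param indel_fraction Fraction of markers simulated as small InDels rather
#'   than SNPs (default 0.2, matching the roughly 4:1 SNP:InDel ratio seen in
#'   rice resequencing).
#'
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(c(chr1 = 1e6), marker_spacing = 1e5)
#' @export
genome_spec <- function(chromosomes, marker_spacing = 20000,
                        cM_per_Mb = 4, indel_fraction = 0.2) {
  if (is.data.frame(chromosomes)) {
    chrom_tbl <- tibble(name = as.character(chromosomes$name),
                        length = as.numeric(chromosomes$length))
  } else {
    if (is.null(names(chromosomes)) || any(names(chromosomes) == "")) {
      abort("`chromosomes` must be a named vector or a data frame with name/length.")
    }
    chrom_tbl <- tibble(name = names(chromosomes),
                        length = as.numeric(chromosomes))
  }
  if (nrow(chrom_tbl) < 1) abort("at least one chromosome is required")
  if (any(chrom_tbl$length <= 0)) abort("chromosome lengths must be > 0")
  if (anyDuplicated(chrom_tbl$name)) abort("duplicated chromosome names")
  if (marker_spacing <= 0) abort("`marker_spacing` must be > 0")
  if (cM_per_Mb < 0) abort("`cM_per_Mb` must be >= 0")
  if (indel_fraction < 0 || indel_fraction > 1) {
    abort("`indel_fraction` must be in [0, 1]")
  }
  structure(
    list(chromosomes = chrom_tbl,
         marker_spacing = as.numeric(marker_spacing),
         cM_per_Mb = as.numeric(cM_per_Mb),
         indel_fraction = as.numeric(indel_fraction)),
    class = "genome_spec"
  )
}

#' Simulation parameters for a bulk-segregant cross
#'
#' Defaults describe the study design this package targets: an F3
#' population of 299 plants from a biparental japonica cross, 10% extreme
#' tails pooled (pools of ~30), bulks sequenced to ~50X and parents to ~31X.
#'
#' @param n_individuals Number of segregating individuals (default 299).
#' @param generation `"F2"` or `"F3"` (default `"F3"`). F3 individuals are
#'   single selfed progeny of independent F2 plants.
#' @param pool_fraction Fraction of the population in each extreme pool
#'   (default 0.10; must lie in (0, 0.5]).
#' @param heritability Narrow-sense heritability of the simulated trait in
#'   \eqn{[0, 1]}.
#' @param bulk_depth_mean Mean sequencing depth per bulk (Poisson, default 50).
#' @param parent_depth_mean Mean sequencing depth per parent (default 31).
#' @param seq_error_rate Symmetric per-read allele flip probability
#'   (default 0.001).
#' @param seed Integer seed controlling every random draw of the simulation.
#'
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(n_individuals = 299, generation = c("F3", "F2"),
                         pool_fraction = 0.10, heritability = 0.5,
                         bulk_depth_mean = 50, parent_depth_mean = 31,
                         seq_error_rate = 0.001, seed = 1L) {
  generation <- match.arg(generation)
  if (n_individuals < 2) abort("`n_individuals` must be >= 2")
  if (pool_fraction <= 0 || pool_fraction > 0.5) {
    abort("`pool_fraction` must be in (0, 0.5]")
  }
  if (heritability < 0 || heritability > 1) {
    abort("`heritability` must be in [0, 1]")
  }
  if (bulk_depth_mean <= 0 || parent_depth_mean <= 0) {
    abort("sequencing depths must be > 0")
  }
  if (seq_error_rate < 0 || seq_error_rate >= 0.5) {
    abort("`seq_error_rate` must be in [0, 0.5)")
  }
  structure(
    list(n_individuals = as.integer(n_individuals), generation = generation,
         pool_fraction = pool_fraction, heritability = heritability,
         bulk_depth_mean = bulk_depth_mean,
         parent_depth_mean = parent_depth_mean,
         seq_error_rate = seq_error_rate, seed = as.integer(seed)),
    class = "cross_config"
  )
}

#' @export
print.cross_config <- function(x, ...) {
  cat("<cross_config> ", x$generation, " population, n = ", x$n_individuals,
      ", pools = ", round(x$pool_fraction * 100), "% tails, h2 = ",
      x$heritability, "\n  depth: bulks ", x$bulk_depth_mean, "X, parents ",
      x$parent_depth_mean, "X, error ", x$seq_error_rate, ", seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write / read a cross configuration as YAML
#'
#' @param config A [cross_config()] object.
#' @param path File path.
#' @return `write_cross_config()` returns `path` invisibly;
#'   `read_cross_config()` returns a `cross_config`.
#' @export
write_cross_config <- function(config, path) {
  stopifnot(inherits(config, "cross_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_cross_config
#' @export
read_cross_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cross_config, vals)
}

#' Declare additive QTLs for the simulated trait
#'
#' @param chrom,pos Marker coordinates of each QTL; `pos` must coincide with
#'   a simulated marker position.
#' @param effect Additive effect in trait units per alternative-allele copy.
#' @param trait Trait label (free text, e.g. `"PH"` or `"DH"`).
#' @return A tibble with one row per QTL.
#' @export
qtl_spec <- function(chrom, pos, effect, trait = "trait") {
  out <- tibble(chrom = as.character(chrom), pos = as.numeric(pos),
                effect = as.numeric(effect),
                trait = rep_len(as.character(trait), length(chrom)))
  if (any(!is.finite(out$effect))) abort("QTL effects must be finite")
  out
}

#' Create two fully homozygous, fully divergent inbred parents
#'
#' Places one marker every `marker_spacing` bp on each chromosome and assigns
#' alleles so that parent 1 is homozygous for the reference allele and parent
#' 2 for the alternative allele at every marker — the idealised situation of
#' two deeply inbred cultivars. A fraction of markers are small InDels
#' (1-50 bp), the rest SNPs with uniformly chosen substitutions.
#'
#' @param genome A [genome_spec()].
#' @param seed Optional integer seed for the allele draws.
#' @return An object of class `parent_haplotypes` with the marker table
#'   (`$markers`: chrom, pos, ref, alt, kind) and the genome.
#' @export
make_parents <- function(genome, seed = NULL) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!is.null(seed)) set.seed(seed)
  markers <- bind_rows(lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    name <- genome$chromosomes$name[i]
    len <- genome$chromosomes$length[i]
    if (genome$marker_spacing > len) {
      abort(paste0("no markers fit on chromosome ", name,
                   ": spacing exceeds its length"))
    }
    tibble(chrom = name,
           pos = seq(genome$marker_spacing, len, by = genome$marker_spacing))
  }))
  n <- nrow(markers)
  bases <- c("A", "C", "G", "T")
  is_indel <- runif(n) < genome$indel_fraction
  ref <- sample(bases, n, replace = TRUE)
  # SNP alt: uniform over the three other bases
  alt <- unname(vapply(ref, function(b) sample(setdiff(bases, b), 1),
                       character(1)))
  ins_len <- pmin(1L + rpois(n, 1.5), 50L)
  tail_seq <- vapply(ins_len, function(k) {
    paste(sample(bases, k, replace = TRUE), collapse = "")
  }, character(1))
  is_ins <- runif(n) < 0.5
  # insertions: ref = anchor base, alt = anchor + inserted bases; deletions mirror
  alt[is_indel & is_ins] <- paste0(ref[is_indel & is_ins],
                                   tail_seq[is_indel & is_ins])
  long_ref <- paste0(ref, tail_seq)
  keep <- is_indel & !is_ins
  alt[keep] <- ref[keep]
  ref[keep] <- long_ref[keep]
  markers$ref <- ref
  markers$alt <- alt
  markers$kind <- ifelse(is_indel, "InDel", "SNP")
  structure(list(genome = genome, markers = markers),
            class = "parent_haplotypes")
}
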