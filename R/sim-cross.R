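# Forward simulation of meiosis and selfing generations.
#
# Haplotypes are integer vectors over the marker table: 0 = parent-1 (ref)
# allele, 1 = parent-2 (alt) allele. Recombination follows a Haldane model:
# crossover count per chromosome ~ Poisson(length_Mb * cM_per_Mb / 100),
# breakpoints uniform, no interference.

# indices of each chromosome's markers, in genome order
chrom_index <- function(genome, markers) {
  lapply(genome$chromosomes$name, function(nm) which(markers$chrom == nm))
}

gamete_chrom <- function(h1, h2, pos, chrom_len, cM_per_Mb) {
  lambda <- chrom_len / 1e6 * cM_per_Mb / 100
  k <- rpois(1L, lambda)
  start <- sample.int(2L, 1L) - 1L
  if (k == 0L) {
    if (start == 0L) h1 else h2
  } else {
    bp <- sort(runif(k, 0, chrom_len))
    pick <- (start + findInterval(pos, bp)) %% 2L
    ifelse(pick == 0L, h1, h2)
  }
}

#' Simulate one gamete from a diploid genotype
#'
#' Produces a recombinant haplotype: per chromosome the crossover count is
#' Poisson(length_Mb * cM_per_Mb / 100) with uniform breakpoints (Haldane,
#' no interference) and a fair coin chooses the starting strand.
#'
#' @param hap1,hap2 Integer haplotype vectors over the marker table
#'   (0 = ref allele, 1 = alt allele).
#' @param genome A [genome_spec()].
#' @param markers Marker table from [make_parents()] (`$markers`).
#' @return An integer haplotype vector, a mosaic of `hap1` and `hap2`.
#' @export
simulate_gamete <- function(hap1, hap2, genome, markers) {
  if (length(hap1) != nrow(markers) || length(hap2) != nrow(markers)) {
    abort("haplotypes must be defined at every marker")
  }
  idx <- chrom_index(genome, markers)
  out <- integer(nrow(markers))
  for (i in seq_along(idx)) {
    ii <- idx[[i]]
    out[ii] <- gamete_chrom(hap1[ii], hap2[ii], markers$pos[ii],
                            genome$chromosomes$length[i], genome$cM_per_Mb)
  }
  out
}

#' Simulate an F2 or F3 segregating population
#'
#' The F1 is heterozygous at every marker. For `generation = "F2"` each
#' individual is one selfed F1 offspring. For `generation = "F3"` each
#' individual is a single selfed seed of an independent F2 plant — the
#' mixed-harvest, randomly-picked design of a two-round selfing series —
#' giving expected genotype frequencies 3/8 : 1/4 : 3/8 at an unlinked
#' marker (1/4 : 1/2 : 1/4 for F2).
#'
#' @param parents A `parent_haplotypes` object from [make_parents()].
#' @param config A [cross_config()]; its `seed` drives all draws.
#' @return An object of class `bsa_population` holding the two haplotype
#'   matrices (markers x individuals) and the alt-allele dosage matrix.
#' @export
make_population <- function(parents, config) {
  stopifnot(inherits(parents, "parent_haplotypes"),
            inherits(config, "cross_config"))
  n <- config$n_individuals
  if (n < 2) abort("`n_individuals` must be >= 2")
  set.seed(config$seed)
  genome <- parents$genome
  markers <- parents$markers
  nm <- nrow(markers)
  idx <- chrom_index(genome, markers)
  lens <- genome$chromosomes$length
  f1_a <- integer(nm)          # all-ref haplotype
  f1_b <- rep(1L, nm)          # all-alt haplotype
  H1 <- matrix(0L, nm, n)
  H2 <- matrix(0L, nm, n)
  one_gamete <- function(h1, h2) {
    out <- integer(nm)
    for (i in seq_along(idx)) {
      ii <- idx[[i]]
      out[ii] <- gamete_chrom(h1[ii], h2[ii], markers$pos[ii], lens[i],
                              genome$cM_per_Mb)
    }
    out
  }
  for (j in seq_len(n)) {
    g1 <- one_gamete(f1_a, f1_b)
    g2 <- one_gamete(f1_a, f1_b)
    if (config$generation == "F2") {
      H1[, j] <- g1
      H2[, j] <- g2
    } else {
      H1[, j] <- one_gamete(g1, g2)
      H2[, j] <- one_gamete(g1, g2)
    }
  }
  structure(
    list(genome = genome, markers = markers, hap1 = H1, hap2 = H2,
         dosage = H1 + H2, generation = config$generation, config = config),
    class = "bsa_population"
  )
}

#' @export
print.bsa_population <- function(x, ...) {
  cat("<bsa_population> ", x$generation, ", ", ncol(x$dosage),
      " individuals, ", nrow(x$markers), " markers on ",
      nrow(x$genome$chromosomes), " chromosome(s)\n", sep = "")
  invisible(x)
}

# expected dosage variance at an unlinked marker, by generation
dosage_variance <- function(generation) {
  switch(generation, F2 = 0.5, F3 = 0.75,
         abort("unknown generation"))
}

#' Assign phenotypes under an additive QTL model
#'
#' Phenotype = sum over QTLs of effect x (dosage - 1) + Gaussian noise. The
#' noise variance is set so that the expected genetic variance (from the
#' generation's segregation ratios, QTLs taken as unlinked) over the total
#' variance equals `heritability`. `heritability = 0` yields pure
#' standard-normal noise.
#'
#' @param population A `bsa_population`.
#' @param qtls A [qtl_spec()] tibble; every QTL must sit on a marker. May
#'   have zero rows.
#' @param heritability Proportion of phenotypic variance that is genetic.
#' @param seed Optional seed for the noise draws (the population seed has
#'   already been consumed by [make_population()]).
#' @return A tibble with columns `id`, `genetic`, `phenotype`.
#' @export
assign_phenotypes <- function(population, qtls, heritability, seed = NULL) {
  stopifnot(inherits(population, "bsa_population"))
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(population$dosage)
  if (nrow(qtls) == 0 || heritability == 0) {
    if (heritability == 1) abort("heritability 1 with no QTLs leaves the noise scale undefined")
    g <- numeric(n)
    return(tibble(id = seq_len(n), genetic = g,
                  phenotype = g + rnorm(n, 0, 1)))
  }
  key <- paste(population$markers$chrom, population$markers$pos)
  rows <- match(paste(qtls$chrom, qtls$pos), key)
  if (anyNA(rows)) {
    abort("every QTL position must coincide with a simulated marker")
  }
  dos <- population$dosage[rows, , drop = FALSE]
  g <- as.numeric(crossprod(dos - 1, qtls$effect))
  var_g <- sum(qtls$effect^2) * dosage_variance(population$generation)
  if (heritability == 1) {
    sigma <- 0
  } else {
    sigma <- sqrt(var_g * (1 - heritability) / heritability)
  }
  tibble(id = seq_len(n), genetic = g, phenotype = g + rnorm(n, 0, sigma))
}

#' Select the extreme-phenotype pools
#'
#' Takes the lowest and highest `round(pool_fraction * n)` individuals
#' (round half up). Ties are broken by individual index, so the low pool
#' prefers earlier and the high pool later indices — a documented, stable
#' rule.
#'
#' @param phenotypes Tibble from [assign_phenotypes()] (needs `id` and
#'   `phenotype`), or a bare numeric vector.
#' @param pool_fraction Fraction of the population per pool, in (0, 0.5].
#' @return A list with integer id vectors `low`, `high` and the pool size `k`.
#' @export
select_pools <- function(phenotypes, pool_fraction = 0.10) {
  if (is.numeric(phenotypes)) {
    phenotypes <- tibble(id = seq_along(phenotypes), phenotype = phenotypes)
  }
  if (pool_fraction <= 0 || pool_fraction > 0.5) {
    abort("`pool_fraction` must be in (0, 0.5]")
  }
  phen <- phenotypes$phenotype
  if (any(!is.finite(phen))) abort("phenotypes must be finite")
  n <- length(phen)
  k <- floor(pool_fraction * n + 0.5)
  if (2 * k > n) abort("pools would overlap: 2 * k exceeds the population")
  ids <- phenotypes$id
  lo_ord <- order(phen, ids)
  hi_ord <- order(-phen, -ids)
  list(low = sort(ids[lo_ord[seq_len(k)]]),
       high = sort(ids[hi_ord[seq_len(k)]]),
       k = k)
}
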