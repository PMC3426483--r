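# Marker filtering: the per-site coverage requirement and the
# minor-allele-count threshold n separating informative from uninformative
# polymorphisms.

#' Marker filter configuration
#'
#' @param n_min_minor minimum pooled count of the minor (less frequent)
#'   allele for a SNP to be retained; the unfiltered analysis corresponds to
#'   n = 1, and the sweep spans n = 1..10.
#' @param min_genomes_per_pop minimum haploid-genome count per population for
#'   a RAD site to be considered (a diploid consensus contributes two
#'   genomes, a haploid one); the default 27 means each individual
#'   contributes at least one haploid genome on average.
#' @param biallelic_only keep only biallelic positions (default TRUE).
#' @param maf_threshold optional frequency-based minor-allele-frequency
#'   threshold, as a convenience alternative to the count rule.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(n_min_minor = 1L, min_genomes_per_pop = 27L,
                          biallelic_only = TRUE, maf_threshold = NULL) {
  stopifnot(n_min_minor >= 1, min_genomes_per_pop >= 0)
  if (!is.null(maf_threshold))
    stopifnot(maf_threshold >= 0, maf_threshold <= 0.5)
  structure(list(n_min_minor = as.integer(n_min_minor),
                 min_genomes_per_pop = as.integer(min_genomes_per_pop),
                 biallelic_only = isTRUE(biallelic_only),
                 maf_threshold = maf_threshold),
            class = "filter_config")
}

#' Per-site coverage gate
#'
#' A RAD site passes when each population contributed at least
#' `min_genomes_per_pop` haploid consensus genomes.
#'
#' @param x either a list of `consensus_genotype`s for one site, a list of
#'   `snp_site`s (whose genome counts are used), or a length-2 numeric
#'   vector of per-population genome counts.
#' @param config a `filter_config`.
#' @return logical: TRUE when the site passes.
#' @export
coverage_gate <- function(x, config = filter_config()) {
  counts <- site_genome_counts(x)
  all(counts >= config$min_genomes_per_pop)
}

site_genome_counts <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 2L)
    return(x)
  }
  if (length(x) && inherits(x[[1]], "consensus_genotype")) {
    pops <- vapply(x, `[[`, character(1), "population_id")
    pl <- vapply(x, `[[`, integer(1), "ploidy")
    # an individual contributes its ploidy when it has any called position
    has_call <- vapply(x, function(g) any(!is.na(g$calls)), logical(1))
    return(tapply(pl * has_call, pops, sum))
  }
  if (length(x) && inherits(x[[1]], "snp_site")) {
    gm <- sapply(x, `[[`, "genome_counts")
    return(apply(gm, 1, max))  # best-covered position represents the site
  }
  stop("cannot derive per-population genome counts from this input")
}

#' Minor-allele-count gate
#'
#' A SNP passes when the pooled count of its less frequent allele is at least
#' `n_min_minor`.  The minor allele is defined on the pooled two-population
#' sample; at an exact 50/50 split either allele counts as minor and the
#' gate compares the shared count.
#'
#' @param site a `snp_site`, or an integer vector of pooled minor-allele
#'   counts.
#' @param config a `filter_config`.
#' @return logical (vectorized over counts).
#' @export
minor_allele_gate <- function(site, config = filter_config()) {
  mac <- if (inherits(site, "snp_site")) site$minor_allele_count else site
  pass <- mac >= config$n_min_minor
  if (!is.null(config$maf_threshold) && inherits(site, "snp_site")) {
    pass <- pass &&
      (mac / sum(site$counts)) >= config$maf_threshold
  }
  pass
}

#' Apply the marker filters to a SNP table
#'
#' Subsets a per-SNP table (from [sim_snp_table()] or the pooling pathway)
#' to rows passing the coverage and minor-allele-count gates, recording per
#' reason how many rows each gate removed.
#'
#' @param tab a SNP table with columns m1, m2 (genome counts) and
#'   minor_allele_count.
#' @param config a `filter_config`.
#' @return the filtered table, with an attribute `filter_log` (a named
#'   integer vector: rows in, failing coverage, failing minor-allele count,
#'   rows out).
#' @export
apply_filters <- function(tab, config = filter_config()) {
  n_in <- nrow(tab)
  cov_ok <- tab$m1 >= config$min_genomes_per_pop &
    tab$m2 >= config$min_genomes_per_pop
  mac_ok <- tab$minor_allele_count >= config$n_min_minor
  out <- tab[cov_ok & mac_ok, , drop = FALSE]
  attr(out, "filter_log") <- c(
    sites_in = n_in,
    failing_coverage = sum(!cov_ok),
    failing_minor_allele = sum(cov_ok & !mac_ok),
    sites_out = nrow(out)
  )
  out
}
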