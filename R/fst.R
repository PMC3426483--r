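# Per-site differentiation estimators: Weir-Cockerham theta (two-population,
# biallelic, diploid) and haplotype-diversity FST on haploid genome counts.

#' Weir-Cockerham theta for a two-population biallelic diploid locus
#'
#' Computes the Weir & Cockerham (1984) variance-components estimator theta
#' (a / (a + b + c)) for two populations at one biallelic locus, from observed
#' diploid genotype counts.  The among-population (a), among-individual (b)
#' and within-individual (c) components use observed heterozygote frequencies;
#' the returned value is unclipped and may be negative.
#'
#' @param genotype_table a 2 x 3 numeric matrix or data frame of genotype
#'   counts, one row per population, columns in the order
#'   (AA, Aa, aa) for the two alleles A and a.
#' @return unclipped theta (scalar).
#' @examples
#' tab <- rbind(c(5, 10, 5), c(5, 10, 5))
#' wc_theta(tab)  # -0.026 at 3 decimals
#' @export
wc_theta <- function(genotype_table) {
  g <- as.matrix(genotype_table)
  if (!is.numeric(g) || nrow(g) != 2L || ncol(g) != 3L)
    stop("genotype_table must be a 2 x 3 count matrix (rows = populations, ",
         "columns = AA, Aa, aa)")
  if (any(g < 0) || any(rowSums(g) < 1))
    stop("each population needs at least one diploid genotype")
  res <- theta_components(
    nAA1 = g[1, 1], nAa1 = g[1, 2], naa1 = g[1, 3],
    nAA2 = g[2, 1], nAa2 = g[2, 2], naa2 = g[2, 3]
  )
  if (is.na(res$theta))
    stop("theta is undefined: locus monomorphic across both populations ",
         "(a + b + c = 0)")
  res$theta
}

# Vectorized Weir-Cockerham components for r = 2 populations.  Inputs are
# per-population diploid genotype counts; all arguments are recycled to a
# common length.  Returns a list with components a, b, c and theta
# (NA where a + b + c == 0, i.e. the locus is monomorphic).
theta_components <- function(nAA1, nAa1, naa1, nAA2, nAa2, naa2) {
  n1 <- nAA1 + nAa1 + naa1
  n2 <- nAA2 + nAa2 + naa2
  r <- 2
  p1 <- (2 * nAA1 + nAa1) / (2 * n1)   # frequency of allele A
  p2 <- (2 * nAA2 + nAa2) / (2 * n2)
  h1 <- nAa1 / n1                      # observed heterozygote frequencies
  h2 <- nAa2 / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom == 0, NA_real_, a / denom)
  list(a = a, b = b, c = cc, theta = theta)
}

# Unbiased allele (haplotype) diversity n/(n-1) * (1 - sum p_k^2) from
# haploid-genome allele counts; equals the probability that two genomes drawn
# without replacement differ.  `counts` is a numeric vector of allele counts.
haplotype_diversity <- function(counts) {
  n <- sum(counts)
  if (n < 2) stop("need at least two genomes for haplotype diversity")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Haplotype-diversity FST for a biallelic locus
#'
#' Computes FST as (H_T - H_S) / H_T, where H is the unbiased haplotype
#' diversity n/(n-1) * (1 - sum p_k^2) on haploid genome counts (a diploid
#' genotype contributes two genomes, a haploid one), H_S the average of the
#' two within-population diversities and H_T the diversity of the pooled
#' sample.  The value is unclipped and may be negative.  This estimator
#' accepts pools mixing haploid and diploid consensus genotypes, which is why
#' it is the default in the genome-scan pipeline.
#'
#' The default weights H_S by genome counts.  Under that form a pooled
#' singleton gives FST = 0 exactly for every placement (H_S = H_T =
#' 2/(m1+m2)), matching the constraint that near-monomorphic loci cannot
#' display appreciable differentiation; the unweighted mean breaks this for
#' unbalanced samples, where it equals (m1-m2)/(2*m1) with the singleton in
#' population 1.
#'
#' @param counts either a `snp_site` object or a 2 x 2 numeric matrix of
#'   haploid-genome allele counts (rows = populations, columns = alleles).
#' @param hs_weighting how to average the within-population diversities for
#'   H_S: `"weighted"` by genome counts (default) or `"unweighted"`.  A
#'   configurable slot because the diversity-partition formula admits both.
#' @param unbiased logical; apply the n/(n-1) small-sample correction
#'   (default TRUE).
#' @return unclipped FST (scalar).
#' @examples
#' haplotype_fst(rbind(c(30, 0), c(0, 30)))  # fixed difference: 1
#' @export
haplotype_fst <- function(counts, hs_weighting = c("weighted", "unweighted"),
                          unbiased = TRUE) {
  hs_weighting <- match.arg(hs_weighting)
  if (inherits(counts, "snp_site")) counts <- counts$counts
  m <- as.matrix(counts)
  if (nrow(m) != 2L || ncol(m) != 2L)
    stop("counts must be a 2 x 2 matrix (populations x alleles)")
  if (any(rowSums(m) < 2))
    stop("need at least two genomes in each population")
  v <- hap_fst_vec(m[1, 2], sum(m[1, ]), m[2, 2], sum(m[2, ]),
                   weighted_hs = hs_weighting == "weighted",
                   unbiased = unbiased)
  if (is.na(v)) stop("FST undefined: pooled sample is monomorphic (H_T = 0)")
  v
}

# Vectorized haplotype-diversity FST from per-population counts of one allele
# (c1, c2) and haploid genome totals (m1, m2).  Returns NA where the pooled
# sample is monomorphic.
hap_fst_vec <- function(c1, m1, c2, m2, weighted_hs = TRUE, unbiased = TRUE) {
  corr <- function(n) if (unbiased) n / (n - 1) else rep(1, length(n))
  div <- function(c, n) corr(n) * (1 - (c / n)^2 - (1 - c / n)^2)
  h1 <- div(c1, m1)
  h2 <- div(c2, m2)
  hs <- if (weighted_hs) (m1 * h1 + m2 * h2) / (m1 + m2) else (h1 + h2) / 2
  ht <- div(c1 + c2, m1 + m2)
  ifelse(ht == 0, NA_real_, (ht - hs) / ht)
}

#' Construct a SNP site record
#'
#' Bundles the per-population data for one variable nucleotide position:
#' haploid-genome allele counts (major and minor allele by pooled count),
#' heterozygote counts and, when available, diploid genotype counts for
#' Weir-Cockerham theta.
#'
#' @param chromosome,position,site_id locus identifiers (position is 1-based).
#' @param alleles length-2 character vector, (major, minor) by pooled count.
#' @param counts 2 x 2 matrix of haploid-genome allele counts
#'   (populations x alleles, columns in `alleles` order).
#' @param het_counts per-population counts of heterozygous diploid individuals.
#' @param diploid_counts optional 2 x 3 matrix of diploid genotype counts
#'   (maj/maj, maj/min, min/min) for theta.
#' @return an object of class `snp_site`.
#' @export
snp_site <- function(chromosome, position, site_id, alleles, counts,
                     het_counts = c(0L, 0L), diploid_counts = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(alleles) == 2L, all(counts >= 0),
            nrow(counts) == 2L, ncol(counts) == 2L)
  minor_pooled <- sum(counts[, 2])
  if (minor_pooled < 1) stop("site is monomorphic: pooled minor count is 0")
  if (sum(counts[, 2]) > sum(counts[, 1]))
    stop("alleles must be ordered (major, minor) by pooled count")
  structure(list(
    chromosome = chromosome, position = as.integer(position),
    site_id = site_id, alleles = alleles, counts = counts,
    het_counts = het_counts, diploid_counts = diploid_counts,
    genome_counts = rowSums(counts),
    minor_allele_count = as.integer(minor_pooled)
  ), class = "snp_site")
}

#' @export
print.snp_site <- function(x, ...) {
  cat(sprintf("<snp_site> %s:%d (site %s)  alleles %s/%s  minor count %d\n",
              x$chromosome, x$position, x$site_id,
              x$alleles[1], x$alleles[2], x$minor_allele_count))
  print(x$counts)
  invisible(x)
}

#' Clip an FST value at zero
#'
#' Negative raw FST values are rounded to zero, as is conventional.
#' @param fst numeric vector of raw FST values.
#' @return clipped values in [0, 1].
#' @export
clip_fst <- function(fst) pmax(fst, 0)

#' Per-RAD-site FST with aggregation across multiple SNPs
#'
#' Evaluates FST at every variable position of one RAD site, clips each raw
#' value at zero, and aggregates per the chosen rule.  The default retains
#' only the highest clipped FST across the site's variable positions;
#' averaging, or selecting a single SNP at random, are alternatives.
#'
#' @param pool a list of `snp_site` objects belonging to one RAD site.
#' @param estimator `"haplotype"` (default) or `"theta"`.  theta requires
#'   diploid genotype counts and is computed on diploid individuals only.
#' @param aggregation `"max"` (default), `"mean"` or `"random"`.
#' @param seed seed for the `"random"` aggregation rule.
#' @return a one-row data frame (an FST record) with columns site_id,
#'   chromosome, position, estimator, aggregation, n_snps,
#'   minor_allele_count, fst_raw and fst (clipped), or NULL when the pool
#'   has no variable positions.  For `"max"` the reported position is that of
#'   the SNP attaining the maximum (ties broken leftmost); for `"mean"` the
#'   position and minor count are those of the leftmost SNP and `fst_raw`
#'   is the mean of raw values.
#' @export
scan_rad_site <- function(pool, estimator = c("haplotype", "theta"),
                          aggregation = c("max", "mean", "random"),
                          seed = NULL) {
  estimator <- match.arg(estimator)
  aggregation <- match.arg(aggregation)
  if (length(pool) == 0L) return(NULL)
  stopifnot(all(vapply(pool, inherits, logical(1), "snp_site")))
  raw <- vapply(pool, function(s) site_fst(s, estimator), numeric(1))
  keep <- !is.na(raw)
  pool <- pool[keep]; raw <- raw[keep]
  if (length(pool) == 0L) return(NULL)
  clipped <- clip_fst(raw)
  pos <- vapply(pool, `[[`, integer(1), "position")
  mac <- vapply(pool, `[[`, integer(1), "minor_allele_count")
  idx <- switch(aggregation,
    max = {
      # leftmost among ties
      cand <- which(clipped == max(clipped))
      cand[which.min(pos[cand])]
    },
    mean = which.min(pos),
    random = {
      if (!is.null(seed)) {
        with_stage_seed(seed, "aggregation", sample.int(length(pool), 1L))
      } else sample.int(length(pool), 1L)
    })
  fst_raw <- switch(aggregation, max = raw[idx], mean = mean(raw),
                    random = raw[idx])
  fst <- switch(aggregation, max = clipped[idx], mean = mean(clipped),
                random = clipped[idx])
  data.frame(
    site_id = pool[[idx]]$site_id, chromosome = pool[[idx]]$chromosome,
    position = pos[idx], estimator = estimator, aggregation = aggregation,
    n_snps = length(pool), minor_allele_count = mac[idx],
    fst_raw = fst_raw, fst = fst, stringsAsFactors = FALSE
  )
}

# FST for a single snp_site under the chosen estimator; NA when undefined.
site_fst <- function(site, estimator) {
  if (estimator == "haplotype") {
    m <- site$counts
    if (any(rowSums(m) < 2)) return(NA_real_)
    hap_fst_vec(m[1, 2], sum(m[1, ]), m[2, 2], sum(m[2, ]))
  } else {
    g <- site$diploid_counts
    if (is.null(g)) stop("theta requires diploid genotype counts")
    if (any(rowSums(g) < 1)) return(NA_real_)
    theta_components(g[1, 1], g[1, 2], g[1, 3],
                     g[2, 1], g[2, 2], g[2, 3])$theta
  }
}
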