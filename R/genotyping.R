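# Quality-aware consensus genotyping of per-individual read stacks: base
# filtering on calling-error probability, a binomial heterozygote test, and
# the depth rule separating diploid from haploid consensus calls.

#' Construct a read stack
#'
#' One individual's aligned reads at one RAD site, as congruent matrices of
#' base calls and per-base calling-error probabilities.
#'
#' @param site_id,individual_id,population_id identifiers.
#' @param bases character matrix (reads x positions) over {A,C,G,T,N}; `"N"`
#'   or NA marks a missing base.
#' @param error_probs numeric matrix of per-base calling-error probabilities,
#'   same dimensions as `bases`.
#' @return an object of class `read_stack`.
#' @export
read_stack <- function(site_id, individual_id, population_id,
                       bases, error_probs) {
  bases <- as.matrix(bases)
  error_probs <- as.matrix(error_probs)
  if (!identical(dim(bases), dim(error_probs)))
    stop("bases and error_probs must have identical dimensions")
  if (length(error_probs) &&
      (any(error_probs < 0, na.rm = TRUE) || any(error_probs > 1, na.rm = TRUE)))
    stop("error probabilities must lie in [0, 1]")
  ok <- is.na(bases) | bases %in% c("A", "C", "G", "T", "N")
  if (!all(ok)) stop("bases must be in {A, C, G, T, N}")
  structure(list(site_id = site_id, individual_id = individual_id,
                 population_id = population_id,
                 bases = bases, error_probs = error_probs),
            class = "read_stack")
}

#' @export
print.read_stack <- function(x, ...) {
  cat(sprintf("<read_stack> site %s, individual %s (%s): %d reads x %d bp\n",
              x$site_id, x$individual_id, x$population_id,
              nrow(x$bases), ncol(x$bases)))
  invisible(x)
}

#' Genotyping configuration
#'
#' @param min_diploid_depth minimum quality-passing read depth for a diploid
#'   consensus call; below it the consensus is haploid.
#' @param het_likelihood_threshold a position is called heterozygous when the
#'   binomial point probability of its allele counts under a 0.5/0.5 null
#'   exceeds this value.
#' @param max_base_error bases whose calling-error probability exceeds this
#'   are excluded before the test.
#' @return an object of class `genotyping_config`.
#' @export
genotyping_config <- function(min_diploid_depth = 10L,
                              het_likelihood_threshold = 0.01,
                              max_base_error = 0.01) {
  stopifnot(min_diploid_depth >= 1,
            het_likelihood_threshold > 0, het_likelihood_threshold < 1,
            max_base_error > 0, max_base_error < 1)
  structure(list(min_diploid_depth = as.integer(min_diploid_depth),
                 het_likelihood_threshold = het_likelihood_threshold,
                 max_base_error = max_base_error),
            class = "genotyping_config")
}

#' Mask low-quality bases in a read stack
#'
#' Bases with calling-error probability strictly greater than
#' `max_base_error` are set to `"N"` (missing); dimensions are preserved.
#'
#' @param stack a `read_stack`.
#' @param config a `genotyping_config`.
#' @return the filtered `read_stack`.
#' @export
filter_bases <- function(stack, config = genotyping_config()) {
  stopifnot(inherits(stack, "read_stack"))
  mask <- stack$error_probs > config$max_base_error
  mask[is.na(mask)] <- FALSE
  stack$bases[mask] <- "N"
  stack
}

#' Binomial heterozygote test
#'
#' Tests the allele counts at one position against the null hypothesis of
#' heterozygosity (each allele with probability 0.5): the position is called
#' heterozygous when the binomial point probability of observing `k` of `n`
#' at 0.5 exceeds the likelihood threshold.  The test is symmetric in
#' `k` and `n - k`.
#'
#' @param k count of one allele (conventionally the minor one).
#' @param n total count of the two alleles entering the test.
#' @param config a `genotyping_config`.
#' @return `"heterozygous"` or `"homozygous"`; NA when `n` is 0.
#' @examples
#' het_test(5, 10)  # heterozygous: choose(10,5)/2^10 > 0.01
#' het_test(1, 10)  # homozygous: 10/1024 < 0.01
#' @export
het_test <- function(k, n, config = genotyping_config()) {
  if (n == 0) return(NA_character_)
  stopifnot(k >= 0, k <= n)
  lik <- stats::dbinom(k, n, 0.5)
  if (lik > config$het_likelihood_threshold) "heterozygous" else "homozygous"
}

# Rank the distinct bases at one position: by count (desc), ties broken by
# lower summed error probability, then lexicographically.  `b` and `ep` are
# the passing bases and their error probabilities.
rank_bases <- function(b, ep) {
  counts <- table(b)
  errsum <- tapply(ep, b, sum)
  ord <- order(-as.vector(counts), as.vector(errsum[names(counts)]),
               names(counts))
  list(base = names(counts)[ord], count = as.integer(counts[ord]))
}

#' Call the consensus genotype of a read stack
#'
#' Applies the depth rule: with quality-passing depth at or above
#' `min_diploid_depth` the consensus is diploid and each position's two most
#' frequent bases enter the binomial heterozygote test (heterozygous calls
#' get both bases, otherwise the majority base twice); below that depth the
#' consensus is haploid and each position gets its majority base.  Positions
#' with no passing base are missing.  Depth is counted per site as the number
#' of reads retaining at least one passing base after [filter_bases()].
#'
#' @param stack a `read_stack`, already base-filtered (apply
#'   [filter_bases()] first; `call_consensus` does not re-filter).
#' @param config a `genotyping_config`.
#' @return an object of class `consensus_genotype`: identifiers, `ploidy`
#'   (1 or 2), `depth`, and `calls`, a ploidy x positions character matrix
#'   with NA for missing positions.
#' @export
call_consensus <- function(stack, config = genotyping_config()) {
  stopifnot(inherits(stack, "read_stack"))
  L <- ncol(stack$bases)
  passing <- !is.na(stack$bases) & stack$bases != "N"
  depth <- if (nrow(stack$bases)) sum(rowSums(passing) > 0L) else 0L
  ploidy <- if (depth >= config$min_diploid_depth) 2L else 1L
  calls <- matrix(NA_character_, nrow = ploidy, ncol = L)
  for (pos in seq_len(L)) {
    ok <- passing[, pos]
    if (!any(ok)) next
    rk <- rank_bases(stack$bases[ok, pos], stack$error_probs[ok, pos])
    if (ploidy == 2L) {
      if (length(rk$base) == 1L) {
        calls[, pos] <- rk$base[1]
      } else {
        verdict <- het_test(rk$count[2], rk$count[1] + rk$count[2], config)
        calls[, pos] <- if (identical(verdict, "heterozygous"))
          c(rk$base[1], rk$base[2]) else rk$base[1]
      }
    } else {
      calls[1, pos] <- rk$base[1]
    }
  }
  structure(list(site_id = stack$site_id,
                 individual_id = stack$individual_id,
                 population_id = stack$population_id,
                 ploidy = ploidy, depth = depth, calls = calls),
            class = "consensus_genotype")
}

#' @export
print.consensus_genotype <- function(x, ...) {
  cat(sprintf(
    "<consensus_genotype> site %s, individual %s: ploidy %d, depth %d, %d positions\n",
    x$site_id, x$individual_id, x$ploidy, x$depth, ncol(x$calls)))
  invisible(x)
}

#' Genotype a collection of read stacks
#'
#' Convenience wrapper: base-filters and consensus-calls every stack.
#'
#' @param stacks a `stack_set` (list of `read_stack`s).
#' @param config a `genotyping_config`.
#' @return a list of `consensus_genotype` objects (class `genotype_set`).
#' @export
genotype_stacks <- function(stacks, config = genotyping_config()) {
  out <- lapply(stacks, function(s) call_consensus(filter_bases(s, config),
                                                   config))
  structure(out, class = "genotype_set")
}

#' Pool consensus genotypes per RAD site and screen for SNPs
#'
#' For each RAD site, pools all individuals' consensus genotypes (a diploid
#' contributes two haploid genomes per position, a haploid one) and screens
#' base by base for polymorphisms, returning one `snp_site` per variable
#' position.  Positions with more than two distinct bases are reduced to the
#' two most frequent pooled alleles, the rest dropped with a warning.
#'
#' @param genotypes a `genotype_set`.
#' @param annotations optional RAD-site annotation data frame (site_id,
#'   chromosome, cut_position, side) used to assign chromosome and genomic
#'   position; when absent, positions are read offsets on site "chrU".
#' @param populations character vector of the two population ids (defaults
#'   to the sorted unique ids present).
#' @return a list (one element per RAD site, named by site_id) of lists of
#'   `snp_site` objects.
#' @export
pool_genotypes <- function(genotypes, annotations = NULL, populations = NULL) {
  by_site <- split(genotypes,
                   vapply(genotypes, `[[`, character(1), "site_id"))
  if (is.null(populations)) {
    populations <- sort(unique(
      vapply(genotypes, `[[`, character(1), "population_id")))
  }
  stopifnot(length(populations) == 2L)
  lapply(by_site, function(gs)
    screen_site(gs, annotations, populations))
}

# Screen one site's pooled genotypes base by base; returns list of snp_site.
screen_site <- function(gs, annotations, populations) {
  site_id <- gs[[1]]$site_id
  L <- ncol(gs[[1]]$calls)
  pops <- vapply(gs, `[[`, character(1), "population_id")
  ploidy <- vapply(gs, `[[`, integer(1), "ploidy")
  chrom <- "chrU"
  coord <- function(pos) pos
  if (!is.null(annotations)) {
    a <- annotations[annotations$site_id == site_id, , drop = FALSE]
    if (nrow(a) == 1L) {
      chrom <- a$chromosome
      coord <- if (a$side == "left") {
        function(pos) as.integer(a$cut_position - pos)
      } else {
        function(pos) as.integer(a$cut_position + pos)
      }
    }
  }
  out <- list()
  for (pos in seq_len(L)) {
    alle <- lapply(gs, function(g) g$calls[, pos])
    flat <- unlist(alle)
    flat <- flat[!is.na(flat)]
    if (length(flat) == 0L) next
    tab <- sort(table(flat), decreasing = TRUE)
    if (length(tab) < 2L) next
    if (length(tab) > 2L)
      warning("site ", site_id, " position ", pos,
              " has >2 alleles; keeping the two most frequent")
    maj <- names(tab)[1]; mino <- names(tab)[2]
    counts <- matrix(0L, 2L, 2L,
                     dimnames = list(populations, c(maj, mino)))
    het <- c(0L, 0L)
    dip <- matrix(0L, 2L, 3L)
    for (i in seq_along(gs)) {
      ai <- alle[[i]]
      ai <- ai[!is.na(ai) & ai %in% c(maj, mino)]
      if (!length(ai)) next
      pi <- match(pops[i], populations)
      counts[pi, 1] <- counts[pi, 1] + sum(ai == maj)
      counts[pi, 2] <- counts[pi, 2] + sum(ai == mino)
      if (ploidy[i] == 2L && length(ai) == 2L) {
        nmin <- sum(ai == mino)
        dip[pi, nmin + 1L] <- dip[pi, nmin + 1L] + 1L
        if (nmin == 1L) het[pi] <- het[pi] + 1L
      }
    }
    if (sum(counts[, 2]) < 1L) next
    out[[length(out) + 1L]] <- snp_site(
      chromosome = chrom, position = coord(pos), site_id = site_id,
      alleles = c(maj, mino), counts = counts, het_counts = het,
      diploid_counts = dip)
  }
  out
}
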