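# Synthetic two-population RAD data: site-frequency spectra skewed toward
# rare alleles, Balding-Nichols drift differentiation, localized hitchhiking
# displacement, sister RAD sites, negative-binomial coverage and sequencing
# error.

#' Simulation configuration
#'
#' Parameters for the two-population synthetic-data generator.  Defaults
#' reflect the study design the pipeline targets: 27 diploid individuals per
#' population, 76-bp single-end RAD reads, per-population mean coverages in
#' the observed 10-30x range, and an allele-frequency spectrum with a large
#' excess of rare alleles.
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @param n_individuals_per_pop diploid individuals per population.
#' @param n_rad_sites number of RAD sites to simulate.
#' @param read_length RAD read length in bp.
#' @param chromosome_length chromosome length in bp.
#' @param chromosome chromosome name.
#' @param mean_coverage_per_pop length-2 vector of mean read depths per
#'   individual and RAD site for the two populations.
#' @param coverage_dispersion negative-binomial size parameter for read
#'   depth; larger values approach Poisson.
#' @param base_error_rate per-base miscall probability of a typical base.
#'   Zero means error-free sequencing.
#' @param high_error_fraction fraction of bases given a high calling-error
#'   probability (`high_error_prob`); these are what the base-quality filter
#'   removes.  Ignored when `base_error_rate` is zero.
#' @param high_error_prob calling-error probability of the low-quality bases.
#' @param drift_F Balding-Nichols drift/differentiation parameter in [0, 1).
#' @param sfs_shape ancestral-spectrum model; `"neutral"` draws the derived
#'   allele count i (out of the pooled genome number) with probability
#'   proportional to 1/i.
#' @param singleton_fraction_target if non-NULL, the generator mixes
#'   near-fixed loci into the spectrum so that the realized fraction of
#'   polymorphic loci whose pooled minor allele count is 1 converges to this
#'   value; the mixing weight is calibrated by simulation from a dedicated
#'   substream.
#' @param near_fixed_weight explicit mixing weight of the near-fixed
#'   component (overrides calibration when `singleton_fraction_target` is
#'   NULL).
#' @param near_fixed_freq ancestral frequency of the near-fixed component;
#'   default 0.5 / (pooled genome count).
#' @param selected_regions list of hitchhiking regions, each a list with
#'   `center` (bp), `max_effect` and `decay_per_bp`; population 1's allele
#'   frequency is displaced by +effect and population 2's by -effect, with
#'   effect = max_effect * exp(-decay_per_bp * distance).
#' @param sister_sites logical; when TRUE, RAD sites come in pairs flanking
#'   a shared restriction cut position (`n_rad_sites` must be even) and the
#'   two sites of a pair share correlated drift deviates.
#' @param sister_cor correlation (on the Gaussian-copula scale) between the
#'   drift quantiles of sister sites.
#' @param strict logical; fail instead of clamping when a hitchhiking
#'   displacement pushes a frequency outside [0, 1].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals_per_pop = 27L,
                       n_rad_sites = 1000L,
                       read_length = 76L,
                       chromosome_length = 1e6,
                       chromosome = "chr1",
                       mean_coverage_per_pop = c(27, 31),
                       coverage_dispersion = 5,
                       base_error_rate = 0.001,
                       high_error_fraction = 0.02,
                       high_error_prob = 0.1,
                       drift_F = 0.05,
                       sfs_shape = "neutral",
                       singleton_fraction_target = NULL,
                       near_fixed_weight = 0,
                       near_fixed_freq = NULL,
                       selected_regions = list(),
                       sister_sites = FALSE,
                       sister_cor = 0.9,
                       strict = FALSE) {
  cfg <- list(
    seed = as.integer(seed),
    n_individuals_per_pop = as.integer(n_individuals_per_pop),
    n_rad_sites = as.integer(n_rad_sites),
    read_length = as.integer(read_length),
    chromosome_length = as.numeric(chromosome_length),
    chromosome = chromosome,
    mean_coverage_per_pop = as.numeric(mean_coverage_per_pop),
    coverage_dispersion = as.numeric(coverage_dispersion),
    base_error_rate = as.numeric(base_error_rate),
    high_error_fraction = as.numeric(high_error_fraction),
    high_error_prob = as.numeric(high_error_prob),
    drift_F = as.numeric(drift_F),
    sfs_shape = sfs_shape,
    singleton_fraction_target = singleton_fraction_target,
    near_fixed_weight = as.numeric(near_fixed_weight),
    near_fixed_freq = near_fixed_freq,
    selected_regions = selected_regions,
    sister_sites = isTRUE(sister_sites),
    sister_cor = as.numeric(sister_cor),
    strict = isTRUE(strict)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_individuals_per_pop > 0, cfg$n_rad_sites > 0,
    cfg$read_length > 0, cfg$chromosome_length > 0,
    length(cfg$mean_coverage_per_pop) == 2L,
    all(cfg$mean_coverage_per_pop > 0),
    cfg$coverage_dispersion > 0,
    cfg$base_error_rate >= 0, cfg$base_error_rate <= 1,
    cfg$high_error_fraction >= 0, cfg$high_error_fraction <= 1,
    cfg$high_error_prob >= 0, cfg$high_error_prob <= 1,
    cfg$drift_F >= 0, cfg$drift_F < 1,
    cfg$near_fixed_weight >= 0, cfg$near_fixed_weight <= 1,
    cfg$sister_cor >= -1, cfg$sister_cor <= 1
  )
  if (!is.null(cfg$singleton_fraction_target))
    stopifnot(cfg$singleton_fraction_target >= 0,
              cfg$singleton_fraction_target <= 1)
  for (reg in cfg$selected_regions) {
    stopifnot(!is.null(reg$center), !is.null(reg$max_effect),
              !is.null(reg$decay_per_bp))
    if (reg$center < 1 || reg$center > cfg$chromosome_length)
      stop("selected-region center must lie within the chromosome")
    stopifnot(reg$max_effect >= 0, reg$max_effect <= 1, reg$decay_per_bp >= 0)
  }
  if (cfg$sister_sites && cfg$n_rad_sites %% 2L != 0L)
    stop("sister_sites requires an even n_rad_sites")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d RAD sites, 2 x %d diploids, drift_F = %g, %s spectrum\n",
    x$n_rad_sites, x$n_individuals_per_pop, x$drift_F, x$sfs_shape))
  if (length(x$selected_regions))
    cat(sprintf("  %d selected region(s)\n", length(x$selected_regions)))
  invisible(x)
}

# Draw ancestral derived-allele frequencies: a neutral 1/i spectrum over
# derived counts i = 1 .. G-1 (G = pooled genome number), optionally mixed
# with a near-fixed point mass that generates mostly singleton loci.
draw_ancestral_freqs <- function(n, G, weight_near_fixed, near_fixed_freq,
                                 sfs_shape = "neutral") {
  if (!identical(sfs_shape, "neutral"))
    stop("unknown sfs_shape: ", sfs_shape)
  i <- seq_len(G - 1)
  p_anc <- sample(i, n, replace = TRUE, prob = 1 / i) / G
  if (weight_near_fixed > 0) {
    nf <- stats::runif(n) < weight_near_fixed
    p_anc[nf] <- near_fixed_freq
  }
  p_anc
}

# Balding-Nichols population frequency via the inverse-CDF: quantile u in
# (0,1) mapped through Beta(p(1-F)/F, (1-p)(1-F)/F).
bn_freq <- function(u, p, F) {
  if (F == 0) return(rep(p, length.out = max(length(u), length(p))))
  stats::qbeta(u, p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# Total hitchhiking displacement at positions `pos`.
selection_effect <- function(pos, regions) {
  e <- numeric(length(pos))
  for (reg in regions)
    e <- e + reg$max_effect * exp(-reg$decay_per_bp * abs(pos - reg$center))
  e
}

#' Simulate two-population allele frequencies and diploid genotypes
#'
#' Draws, for each RAD site, an ancestral allele frequency from the
#' configured spectrum, population frequencies from the Balding-Nichols beta
#' model with parameter `drift_F`, adds hitchhiking displacement inside
#' selected regions (population 1 toward fixation of the derived allele,
#' population 2 away from it), and samples each individual's diploid genotype
#' binomially from its population frequency.  Output is byte-identical for a
#' fixed seed and configuration.
#'
#' @param config a `sim_config`.
#' @return an object of class `pop_sim`: a list with `config`, `sites` (one
#'   row per RAD site: site_id, chromosome, cut_position, side, pair_id,
#'   position and offset of the site's SNP, ref/alt bases, ancestral and
#'   population frequencies, selection effect), `genotypes` (sites x
#'   individuals integer matrix of derived-allele copies 0/1/2), `pop`
#'   (population of each individual column) and `individuals`.
#' @export
simulate_populations <- function(config) {
  validate_sim_config(config)
  with_stage_seed(config$seed, "populations", {
    n_ind <- config$n_individuals_per_pop
    n_sites <- config$n_rad_sites
    G <- 4L * n_ind                     # pooled haploid genomes
    nf_freq <- if (is.null(config$near_fixed_freq)) 0.5 / G else
      config$near_fixed_freq
    w <- config$near_fixed_weight
    if (!is.null(config$singleton_fraction_target))
      w <- calibrate_near_fixed_weight(config, G, nf_freq)

    # site layout: cut positions, sides, SNP offset within the 76-bp read
    if (config$sister_sites) {
      n_cut <- n_sites %/% 2L
      cuts <- sort(sample.int(config$chromosome_length, n_cut))
      cut_position <- rep(cuts, each = 2L)
      side <- rep(c("left", "right"), n_cut)
      pair_id <- rep(seq_len(n_cut), each = 2L)
    } else {
      cut_position <- sort(sample.int(config$chromosome_length, n_sites))
      side <- sample(c("left", "right"), n_sites, replace = TRUE)
      pair_id <- seq_len(n_sites)
    }
    offset <- sample.int(config$read_length, n_sites, replace = TRUE)
    position <- ifelse(side == "left",
                       pmax(cut_position - offset, 1),
                       pmin(cut_position + offset, config$chromosome_length))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

    p_anc <- draw_ancestral_freqs(n_sites, G, w, nf_freq, config$sfs_shape)

    # drift quantiles; sister sites share a pair-level Gaussian component
    if (config$sister_sites) {
      rho <- config$sister_cor
      z_pair <- matrix(stats::rnorm(2L * max(pair_id)), ncol = 2L)
      z_site <- matrix(stats::rnorm(2L * n_sites), ncol = 2L)
      u <- stats::pnorm(rho * z_pair[pair_id, ] +
                          sqrt(1 - rho^2) * z_site)
    } else {
      u <- matrix(stats::runif(2L * n_sites), ncol = 2L)
    }
    p1 <- bn_freq(u[, 1], p_anc, config$drift_F)
    p2 <- bn_freq(u[, 2], p_anc, config$drift_F)

    eff <- selection_effect(position, config$selected_regions)
    if (any(eff > 0)) {
      p1s <- p1 + eff
      p2s <- p2 - eff
      n_clamp <- sum(p1s > 1 | p2s < 0)
      if (n_clamp > 0) {
        if (config$strict)
          stop("hitchhiking displacement pushed ", n_clamp,
               " frequencies outside [0, 1] (strict mode)")
        warning("clamped ", n_clamp,
                " displaced allele frequencies to [0, 1]")
      }
      p1 <- pmin(pmax(p1s, 0), 1)
      p2 <- pmin(pmax(p2s, 0), 1)
    }

    g1 <- matrix(stats::rbinom(n_sites * n_ind, 2L, p1),
                 nrow = n_sites, ncol = n_ind)
    g2 <- matrix(stats::rbinom(n_sites * n_ind, 2L, p2),
                 nrow = n_sites, ncol = n_ind)
    genotypes <- cbind(g1, g2)
    individuals <- c(sprintf("pop1_ind%03d", seq_len(n_ind)),
                     sprintf("pop2_ind%03d", seq_len(n_ind)))
    colnames(genotypes) <- individuals
    site_id <- sprintf("site%06d", seq_len(n_sites))
    rownames(genotypes) <- site_id

    sites <- data.frame(
      site_id = site_id, chromosome = config$chromosome,
      cut_position = cut_position, side = side, pair_id = pair_id,
      offset = offset, position = as.integer(position),
      ref = ref, alt = alt,
      p_anc = p_anc, p1 = p1, p2 = p2, sel_effect = eff,
      stringsAsFactors = FALSE
    )
    structure(list(config = config, sites = sites, genotypes = genotypes,
                   pop = rep(c("pop1", "pop2"), each = n_ind),
                   individuals = individuals),
              class = "pop_sim")
  })
}

# Monte-Carlo calibration of the near-fixed mixing weight so that the
# singleton fraction among polymorphic loci hits the target.  Uses its own
# substream so calibration does not perturb the main simulation stream.
calibrate_near_fixed_weight <- function(config, G, nf_freq, n_trial = 4000L) {
  t <- config$singleton_fraction_target
  with_stage_seed(config$seed, "calibration", {
    comp_stats <- function(p_anc) {
      p1 <- bn_freq(stats::runif(n_trial), p_anc, config$drift_F)
      p2 <- bn_freq(stats::runif(n_trial), p_anc, config$drift_F)
      cnt <- stats::rbinom(n_trial, G %/% 2L, p1) +
        stats::rbinom(n_trial, G %/% 2L, p2)
      mac <- pmin(cnt, G - cnt)
      poly <- mac >= 1L
      c(q = mean(poly), s = if (any(poly)) mean(mac[poly] == 1L) else 0)
    }
    i <- seq_len(G - 1)
    base <- comp_stats(sample(i, n_trial, replace = TRUE, prob = 1 / i) / G)
    nf <- comp_stats(rep(nf_freq, n_trial))
    if (t <= base["s"]) return(0)
    if (t >= nf["s"]) {
      warning("singleton_fraction_target ", t,
              " exceeds what the near-fixed component can deliver (",
              round(nf["s"], 3), "); using weight 1")
      return(1)
    }
    ratio <- (base["q"] * (t - base["s"])) / (nf["q"] * (nf["s"] - t))
    unname(ratio / (1 + ratio))
  })
}

#' @export
print.pop_sim <- function(x, ...) {
  cat(sprintf("<pop_sim> %d RAD sites x %d individuals (2 populations)\n",
              nrow(x$sites), ncol(x$genotypes)))
  invisible(x)
}

#' Per-SNP summary table of a population simulation
#'
#' Collapses the simulated genotype matrix into one row per RAD-site SNP with
#' the pooled-sample quantities the downstream modules need: per-population
#' derived-allele genome counts, heterozygote and diploid genotype counts,
#' and the pooled minor allele count.
#'
#' @param sim a `pop_sim`.
#' @param polymorphic_only drop loci monomorphic in the sample (default TRUE).
#' @return a data frame with one row per (polymorphic) SNP.
#' @export
sim_snp_table <- function(sim, polymorphic_only = TRUE) {
  stopifnot(inherits(sim, "pop_sim"))
  g <- sim$genotypes
  is1 <- sim$pop == "pop1"
  n1 <- sum(is1); n2 <- sum(!is1)
  g1 <- g[, is1, drop = FALSE]; g2 <- g[, !is1, drop = FALSE]
  c1 <- rowSums(g1); c2 <- rowSums(g2)          # derived genomes per pop
  tab <- cbind(
    sim$sites[, c("site_id", "chromosome", "position", "cut_position",
                  "side", "pair_id", "ref", "alt")],
    data.frame(
      c1 = c1, m1 = 2L * n1, c2 = c2, m2 = 2L * n2,
      het1 = rowSums(g1 == 1L), het2 = rowSums(g2 == 1L),
      nAA1 = rowSums(g1 == 0L), nAa1 = rowSums(g1 == 1L),
      naa1 = rowSums(g1 == 2L),
      nAA2 = rowSums(g2 == 0L), nAa2 = rowSums(g2 == 1L),
      naa2 = rowSums(g2 == 2L)
    )
  )
  tab$minor_allele_count <- as.integer(
    pmin(tab$c1 + tab$c2, tab$m1 + tab$m2 - tab$c1 - tab$c2))
  if (polymorphic_only) tab <- tab[tab$minor_allele_count >= 1L, ]
  rownames(tab) <- NULL
  tab
}

#' Add per-SNP FST columns to a SNP table
#'
#' Computes the chosen estimator for every row of a SNP table (columns
#' `fst_raw` and clipped `fst`).  The haplotype estimator uses the
#' haploid-genome counts; theta uses the diploid genotype counts.
#'
#' @param tab a SNP table from [sim_snp_table()] or the pooling functions.
#' @param estimator `"haplotype"` or `"theta"`.
#' @return `tab` with `estimator`, `fst_raw` and `fst` columns added.
#' @export
add_fst <- function(tab, estimator = c("haplotype", "theta")) {
  estimator <- match.arg(estimator)
  raw <- if (estimator == "haplotype") {
    hap_fst_vec(tab$c1, tab$m1, tab$c2, tab$m2)
  } else {
    theta_components(tab$nAA1, tab$nAa1, tab$naa1,
                     tab$nAA2, tab$nAa2, tab$naa2)$theta
  }
  tab$estimator <- estimator
  tab$fst_raw <- raw
  tab$fst <- clip_fst(raw)
  tab
}

#' Realized singleton fraction of a simulation or SNP table
#'
#' @param x a `pop_sim` or a SNP table.
#' @return fraction of polymorphic loci whose pooled minor allele count is 1.
#' @export
singleton_fraction <- function(x) {
  if (inherits(x, "pop_sim")) x <- sim_snp_table(x)
  mac <- x$minor_allele_count
  mean(mac[mac >= 1L] == 1L)
}

#' Simulate per-individual read stacks from simulated genotypes
#'
#' For each individual and RAD site, draws a read depth from a
#' negative-binomial with the population's mean coverage and the configured
#' dispersion; each read copies one of the individual's two haplotypes
#' uniformly; each base is miscalled with its per-base calling-error
#' probability (a mixture of a typical rate and a small fraction of
#' low-quality bases) to a uniformly chosen other base.  The attached
#' error-probability matrix is the one the miscall process actually used.
#'
#' @param sim a `pop_sim` from [simulate_populations()].
#' @param sites optional character vector of site_ids to restrict to.
#' @return a list of `read_stack` objects (class `stack_set`), one per
#'   individual x site, each with `bases` and congruent `error_probs`
#'   matrices of dimension reads x read_length.
#' @export
simulate_read_stacks <- function(sim, sites = NULL) {
  stopifnot(inherits(sim, "pop_sim"))
  config <- sim$config
  with_stage_seed(config$seed, "stacks", {
    st <- sim$sites
    if (!is.null(sites)) st <- st[st$site_id %in% sites, , drop = FALSE]
    L <- config$read_length
    bases <- c("A", "C", "G", "T")
    n_ind <- length(sim$individuals)
    out <- vector("list", nrow(st) * n_ind)
    k <- 0L
    for (i in seq_len(nrow(st))) {
      # reference read sequence for this site; the SNP column carries ref/alt
      ref_seq <- sample(bases, L, replace = TRUE)
      ref_seq[st$offset[i]] <- st$ref[i]
      for (j in seq_len(n_ind)) {
        popj <- sim$pop[j]
        mu <- config$mean_coverage_per_pop[if (popj == "pop1") 1L else 2L]
        d <- stats::rnbinom(1L, size = config$coverage_dispersion, mu = mu)
        geno <- sim$genotypes[st$site_id[i], j]  # derived-allele copies
        if (d > 0) {
          mat <- matrix(rep(ref_seq, each = d), nrow = d)
          alt_read <- switch(as.character(geno),
            "0" = rep(FALSE, d),
            "1" = stats::runif(d) < 0.5,  # uniform haplotype choice
            "2" = rep(TRUE, d))
          mat[alt_read, st$offset[i]] <- st$alt[i]
          if (config$base_error_rate > 0) {
            ep <- matrix(config$base_error_rate, d, L)
            hi <- matrix(stats::runif(d * L) < config$high_error_fraction,
                         d, L)
            ep[hi] <- config$high_error_prob
            err <- matrix(stats::runif(d * L) < ep, d, L)
            if (any(err)) {
              idx <- which(err)
              mat[idx] <- vapply(mat[idx], function(b)
                sample(setdiff(bases, b), 1L), character(1))
            }
          } else {
            ep <- matrix(0, d, L)
          }
        } else {
          mat <- matrix(character(0), 0L, L)
          ep <- matrix(numeric(0), 0L, L)
        }
        k <- k + 1L
        out[[k]] <- read_stack(st$site_id[i], sim$individuals[j], popj,
                               mat, ep)
      }
    }
    structure(out, class = "stack_set")
  })
}

#' Marker/QTL linkage scenarios for hitchhiking
#'
#' Builds a two-population, two-locus configuration illustrating when a
#' neutral marker tightly linked to a selected QTL is informative about the
#' selection.  Case `"A"`: the rare marker allele is unlinked to the favored
#' QTL allele, so selection leaves the marker's skewed frequencies unchanged
#' and marker FST stays near zero.  Case `"B"`: the rare marker allele is
#' linked to the favored QTL allele and hitchhikes to high frequency, giving
#' strong marker differentiation.  Case `"C"`: the marker starts balanced and
#' identical in both populations (FST clips to zero) and shows clear
#' differentiation after the sweep.
#'
#' @param case one of `"A"`, `"B"`, `"C"`.
#' @param n_genomes haploid marker genomes sampled per population.
#' @param rare_count marker minor-allele count per population in the skewed
#'   initial state (cases A and B).
#' @param swept_freq post-selection frequency reached by the hitchhiking
#'   marker allele in population 2 (cases B and C).
#' @return a list of class `hitchhiking_scenario` with marker allele counts
#'   (`yellow`, `blue`) per population at `t0` and `t1`, plus the clipped
#'   haplotype-diversity marker FST at both times.
#' @export
hitchhiking_scenario <- function(case = c("A", "B", "C"), n_genomes = 54L,
                                 rare_count = 2L, swept_freq = 0.75) {
  case <- match.arg(case)
  n <- as.integer(n_genomes)
  rare <- as.integer(rare_count)
  swept <- as.integer(round(swept_freq * n))
  counts <- function(blueA, blueB)
    list(popA = c(yellow = n - blueA, blue = blueA),
         popB = c(yellow = n - blueB, blue = blueB))
  t0 <- switch(case,
    A = counts(rare, rare),
    B = counts(rare, rare),
    C = counts(n %/% 2L, n %/% 2L))
  t1 <- switch(case,
    A = counts(rare, rare),            # sweep invisible at the marker
    B = counts(rare, swept),           # blue hitchhikes up in population 2
    C = counts(n %/% 2L, n %/% 2L - swept %/% 2L))
  fst_of <- function(tt) {
    m <- rbind(unname(tt$popA), unname(tt$popB))
    clip_fst(hap_fst_vec(m[1, 2], sum(m[1, ]), m[2, 2], sum(m[2, ])))
  }
  structure(list(case = case, t0 = t0, t1 = t1,
                 fst_t0 = fst_of(t0), fst_t1 = fst_of(t1)),
            class = "hitchhiking_scenario")
}

#' @export
print.hitchhiking_scenario <- function(x, ...) {
  cat(sprintf("<hitchhiking_scenario> case %s: marker FST %.3f (t0) -> %.3f (t1)\n",
              x$case, x$fst_t0, x$fst_t1))
  invisible(x)
}
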